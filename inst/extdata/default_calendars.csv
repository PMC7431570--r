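calendar,start_date,end_date,level
policy,1979-01-01,2003-03-31,0
policy,2003-04-01,2005-01-29,1
policy,2005-01-30,2005-03-31,0
policy,2005-04-01,2005-08-06,1
policy,2005-08-07,2006-03-31,0
policy,2006-04-01,2006-08-13,1
policy,2006-08-14,2007-03-11,0
policy,2007-03-12,2008-09-28,1
policy,2008-09-29,2009-05-03,0
policy,2009-05-04,2009-06-28,1
policy,2009-06-29,2012-01-27,0
policy,2012-01-28,2012-04-14,1
season,1979-01-01,1979-03-31,1
season,1979-04-01,1979-09-30,0
season,1979-10-01,1980-03-31,1
season,1980-04-01,1980-09-30,0
season,1980-10-01,1981-03-31,1
season,1981-04-01,1981-09-30,0
season,1981-10-01,1982-03-31,1
season,1982-04-01,1982-09-30,0
season,1982-10-01,1983-03-31,1
season,1983-04-01,1983-09-30,0
season,1983-10-01,1984-03-31,1
season,1984-04-01,1984-09-30,0
season,1984-10-01,1985-03-31,1
season,1985-04-01,1985-09-30,0
season,1985-10-01,1986-03-31,1
season,1986-04-01,1986-09-30,0
season,1986-10-01,1987-03-31,1
season,1987-04-01,1987-09-30,0
season,1987-10-01,1988-03-31,1
season,1988-04-01,1988-09-30,0
season,1988-10-01,1989-03-31,1
season,1989-04-01,1989-09-30,0
season,1989-10-01,1990-03-31,1
season,1990-04-01,1990-09-30,0
season,1990-10-01,1991-03-31,1
season,1991-04-01,1991-09-30,0
season,1991-10-01,1992-03-31,1
season,1992-04-01,1992-09-30,0
season,1992-10-01,1993-03-31,1
season,1993-04-01,1993-09-30,0
season,1993-10-01,1994-03-31,1
season,1994-04-01,1994-09-30,0
season,1994-10-01,1995-03-31,1
season,1995-04-01,1995-09-30,0
season,1995-10-01,1996-03-31,1
season,1996-04-01,1996-09-30,0
season,1996-10-01,1997-03-31,1
season,1997-04-01,1997-09-30,0
season,1997-10-01,1998-03-31,1
season,1998-04-01,1998-09-30,0
season,1998-10-01,1999-03-31,1
season,1999-04-01,1999-09-30,0
season,1999-10-01,2000-03-31,1
season,2000-04-01,2000-09-30,0
season,2000-10-01,2001-03-31,1
season,2001-04-01,2001-09-30,0
season,2001-10-01,2002-03-31,1
season,2002-04-01,2002-09-30,0
season,2002-10-01,2003-03-31,1
season,2003-04-01,2003-09-30,0
season,2003-10-01,2004-03-31,1
season,2004-04-01,2004-09-30,0
season,2004-10-01,2005-03-31,1
season,2005-04-01,2005-09-30,0
season,2005-10-01,2006-03-31,1
season,2006-04-01,2006-09-30,0
season,2006-10-01,2007-03-31,1
season,2007-04-01,2007-09-30,0
season,2007-10-01,2008-03-31,1
season,2008-04-01,2008-09-30,0
season,2008-10-01,2009-03-31,1
season,2009-04-01,2009-09-30,0
season,2009-10-01,2010-03-31,1
season,2010-04-01,2010-09-30,0
season,2010-10-01,2011-03-31,1
season,2011-04-01,2011-09-30,0
season,2011-10-01,2012-03-31,1
season,2012-04-01,2012-04-14,0
census,1979-01-01,1994-12-31,1
census,1995-01-01,2000-12-31,2
census,2001-01-01,2012-04-14,3
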