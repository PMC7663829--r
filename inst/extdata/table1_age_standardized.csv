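year,sex,biomarker,value
1973,men,sbp,137.2
1973,men,sg,
1973,men,tg,
1973,men,hdl,
1973,men,bmi,21.9
1973,women,sbp,134.1
1973,women,sg,
1973,women,tg,
1973,women,hdl,
1973,women,bmi,22.6
1975,men,sbp,137.0
1975,men,sg,
1975,men,tg,
1975,men,hdl,
1975,men,bmi,22.2
1975,women,sbp,133.4
1975,women,sg,
1975,women,tg,
1975,women,hdl,
1975,women,bmi,22.6
1976,men,sbp,136.9
1976,men,sg,
1976,men,tg,
1976,men,hdl,
1976,men,bmi,22.3
1976,women,sbp,133.6
1976,women,sg,
1976,women,tg,
1976,women,hdl,
1976,women,bmi,22.7
1977,men,sbp,136.4
1977,men,sg,
1977,men,tg,
1977,men,hdl,
1977,men,bmi,22.3
1977,women,sbp,133.4
1977,women,sg,
1977,women,tg,
1977,women,hdl,
1977,women,bmi,22.6
1978,men,sbp,137.1
1978,men,sg,
1978,men,tg,
1978,men,hdl,
1978,men,bmi,22.4
1978,women,sbp,132.1
1978,women,sg,
1978,women,tg,
1978,women,hdl,
1978,women,bmi,22.7
1979,men,sbp,137.0
1979,men,sg,
1979,men,tg,
1979,men,hdl,
1979,men,bmi,22.4
1979,women,sbp,133.4
1979,women,sg,
1979,women,tg,
1979,women,hdl,
1979,women,bmi,22.5
1980,men,sbp,136.2
1980,men,sg,
1980,men,tg,
1980,men,hdl,
1980,men,bmi,22.4
1980,women,sbp,131.2
1980,women,sg,
1980,women,tg,
1980,women,hdl,
1980,women,bmi,22.7
1981,men,sbp,135.5
1981,men,sg,
1981,men,tg,
1981,men,hdl,
1981,men,bmi,22.7
1981,women,sbp,132.0
1981,women,sg,
1981,women,tg,
1981,women,hdl,
1981,women,bmi,22.7
1982,men,sbp,136.2
1982,men,sg,
1982,men,tg,
1982,men,hdl,
1982,men,bmi,22.6
1982,women,sbp,131.7
1982,women,sg,
1982,women,tg,
1982,women,hdl,
1982,women,bmi,22.7
1983,men,sbp,136.4
1983,men,sg,
1983,men,tg,
1983,men,hdl,
1983,men,bmi,22.7
1983,women,sbp,131.9
1983,women,sg,
1983,women,tg,
1983,women,hdl,
1983,women,bmi,22.6
1984,men,sbp,135.0
1984,men,sg,
1984,men,tg,
1984,men,hdl,
1984,men,bmi,22.6
1984,women,sbp,130.2
1984,women,sg,
1984,women,tg,
1984,women,hdl,
1984,women,bmi,22.6
1985,men,sbp,135.1
1985,men,sg,
1985,men,tg,
1985,men,hdl,
1985,men,bmi,22.6
1985,women,sbp,130.4
1985,women,sg,
1985,women,tg,
1985,women,hdl,
1985,women,bmi,22.7
1986,men,sbp,134.4
1986,men,sg,
1986,men,tg,
1986,men,hdl,
1986,men,bmi,22.7
1986,women,sbp,130.5
1986,women,sg,
1986,women,tg,
1986,women,hdl,
1986,women,bmi,22.6
1987,men,sbp,134.8
1987,men,sg,
1987,men,tg,
1987,men,hdl,
1987,men,bmi,22.8
1987,women,sbp,130.0
1987,women,sg,
1987,women,tg,
1987,women,hdl,
1987,women,bmi,22.6
1988,men,sbp,135.3
1988,men,sg,
1988,men,tg,
1988,men,hdl,
1988,men,bmi,22.8
1988,women,sbp,130.6
1988,women,sg,
1988,women,tg,
1988,women,hdl,
1988,women,bmi,22.5
1989,men,sbp,134.6
1989,men,sg,
1989,men,tg,
1989,men,hdl,
1989,men,bmi,22.8
1989,women,sbp,129.0
1989,women,sg,
1989,women,tg,
1989,women,hdl,
1989,women,bmi,22.5
1990,men,sbp,134.2
1990,men,sg,
1990,men,tg,
1990,men,hdl,
1990,men,bmi,22.9
1990,women,sbp,129.2
1990,women,sg,
1990,women,tg,
1990,women,hdl,
1990,women,bmi,22.6
1991,men,sbp,134.9
1991,men,sg,95.0
1991,men,tg,159.0
1991,men,hdl,50.8
1991,men,bmi,23.0
1991,women,sbp,129.9
1991,women,sg,93.9
1991,women,tg,116.1
1991,women,hdl,58.4
1991,women,bmi,22.6
1992,men,sbp,134.8
1992,men,sg,
1992,men,tg,
1992,men,hdl,
1992,men,bmi,23.0
1992,women,sbp,129.3
1992,women,sg,
1992,women,tg,
1992,women,hdl,
1992,women,bmi,22.6
1993,men,sbp,133.8
1993,men,sg,
1993,men,tg,
1993,men,hdl,
1993,men,bmi,23.1
1993,women,sbp,128.7
1993,women,sg,
1993,women,tg,
1993,women,hdl,
1993,women,bmi,22.6
1994,men,sbp,133.2
1994,men,sg,
1994,men,tg,
1994,men,hdl,
1994,men,bmi,23.0
1994,women,sbp,128.3
1994,women,sg,
1994,women,tg,
1994,women,hdl,
1994,women,bmi,22.5
1995,men,sbp,135.1
1995,men,sg,
1995,men,tg,
1995,men,hdl,
1995,men,bmi,23.2
1995,women,sbp,128.4
1995,women,sg,
1995,women,tg,
1995,women,hdl,
1995,women,bmi,22.5
1996,men,sbp,134.6
1996,men,sg,
1996,men,tg,
1996,men,hdl,
1996,men,bmi,23.1
1996,women,sbp,128.6
1996,women,sg,
1996,women,tg,
1996,women,hdl,
1996,women,bmi,22.5
1997,men,sbp,134.2
1997,men,sg,102.0
1997,men,tg,157.5
1997,men,hdl,53.5
1997,men,bmi,23.2
1997,women,sbp,127.8
1997,women,sg,101.3
1997,women,tg,124.1
1997,women,hdl,62.2
1997,women,bmi,22.5
1998,men,sbp,133.5
1998,men,sg,100.8
1998,men,tg,161.6
1998,men,hdl,53.6
1998,men,bmi,23.4
1998,women,sbp,127.5
1998,women,sg,99.7
1998,women,tg,120.5
1998,women,hdl,62.6
1998,women,bmi,22.5
1999,men,sbp,133.6
1999,men,sg,100.1
1999,men,tg,164.2
1999,men,hdl,53.6
1999,men,bmi,23.4
1999,women,sbp,127.2
1999,women,sg,98.6
1999,women,tg,122.6
1999,women,hdl,62.0
1999,women,bmi,22.4
2000,men,sbp,131.6
2000,men,sg,100.4
2000,men,tg,166.5
2000,men,hdl,53.4
2000,men,bmi,23.3
2000,women,sbp,124.8
2000,women,sg,99.6
2000,women,tg,121.4
2000,women,hdl,62.3
2000,women,bmi,22.4
2001,men,sbp,132.1
2001,men,sg,99.3
2001,men,tg,162.1
2001,men,hdl,53.9
2001,men,bmi,23.5
2001,women,sbp,124.8
2001,women,sg,98.7
2001,women,tg,115.6
2001,women,hdl,63.1
2001,women,bmi,22.3
2002,men,sbp,132.2
2002,men,sg,99.5
2002,men,tg,159.6
2002,men,hdl,56.0
2002,men,bmi,23.6
2002,women,sbp,124.8
2002,women,sg,97.9
2002,women,tg,115.0
2002,women,hdl,66.7
2002,women,bmi,22.3
2003,men,sbp,130.4
2003,men,sg,102.5
2003,men,tg,164.6
2003,men,hdl,56.8
2003,men,bmi,23.6
2003,women,sbp,123.6
2003,women,sg,99.5
2003,women,tg,120.3
2003,women,hdl,66.2
2003,women,bmi,22.4
2004,men,sbp,130.8
2004,men,sg,100.5
2004,men,tg,161.2
2004,men,hdl,56.1
2004,men,bmi,23.6
2004,women,sbp,123.9
2004,women,sg,98.7
2004,women,tg,119.3
2004,women,hdl,66.4
2004,women,bmi,22.2
2005,men,sbp,129.7
2005,men,sg,102.8
2005,men,tg,157.3
2005,men,hdl,56.0
2005,men,bmi,23.5
2005,women,sbp,123.2
2005,women,sg,100.9
2005,women,tg,116.8
2005,women,hdl,65.6
2005,women,bmi,22.3
2006,men,sbp,131.2
2006,men,sg,102.4
2006,men,tg,155.8
2006,men,hdl,57.9
2006,men,bmi,23.7
2006,women,sbp,123.3
2006,women,sg,100.8
2006,women,tg,115.0
2006,women,hdl,68.4
2006,women,bmi,22.3
2007,men,sbp,131.2
2007,men,sg,101.1
2007,men,tg,156.0
2007,men,hdl,58.5
2007,men,bmi,23.6
2007,women,sbp,122.7
2007,women,sg,99.2
2007,women,tg,109.2
2007,women,hdl,70.2
2007,women,bmi,22.0
2008,men,sbp,130.6
2008,men,sg,99.9
2008,men,tg,150.1
2008,men,hdl,58.2
2008,men,bmi,23.6
2008,women,sbp,122.0
2008,women,sg,97.7
2008,women,tg,108.7
2008,women,hdl,68.9
2008,women,bmi,22.1
2009,men,sbp,130.1
2009,men,sg,99.1
2009,men,tg,163.8
2009,men,hdl,55.9
2009,men,bmi,23.6
2009,women,sbp,121.1
2009,women,sg,96.1
2009,women,tg,112.9
2009,women,hdl,65.7
2009,women,bmi,22.1
2010,men,sbp,129.8
2010,men,sg,96.4
2010,men,tg,161.7
2010,men,hdl,57.1
2010,men,bmi,23.6
2010,women,sbp,121.9
2010,women,sg,96.0
2010,women,tg,108.0
2010,women,hdl,67.7
2010,women,bmi,22.0
2011,men,sbp,129.6
2011,men,sg,98.0
2011,men,tg,165.1
2011,men,hdl,55.5
2011,men,bmi,23.7
2011,women,sbp,121.0
2011,women,sg,97.0
2011,women,tg,112.2
2011,women,hdl,65.7
2011,women,bmi,22.2
2012,men,sbp,129.2
2012,men,sg,
2012,men,tg,
2012,men,hdl,55.2
2012,men,bmi,23.6
2012,women,sbp,120.7
2012,women,sg,
2012,women,tg,
2012,women,hdl,66.2
2012,women,bmi,22.0
2013,men,sbp,128.8
2013,men,sg,99.6
2013,men,tg,167.1
2013,men,hdl,55.7
2013,men,bmi,23.6
2013,women,sbp,121.5
2013,women,sg,96.1
2013,women,tg,111.7
2013,women,hdl,66.8
2013,women,bmi,22.0
2014,men,sbp,129.1
2014,men,sg,97.8
2014,men,tg,163.2
2014,men,hdl,55.5
2014,men,bmi,23.6
2014,women,sbp,120.5
2014,women,sg,97.0
2014,women,tg,116.2
2014,women,hdl,66.1
2014,women,bmi,22.2
2015,men,sbp,128.2
2015,men,sg,95.7
2015,men,tg,167.4
2015,men,hdl,56.1
2015,men,bmi,23.8
2015,women,sbp,119.7
2015,women,sg,95.1
2015,women,tg,116.4
2015,women,hdl,67.7
2015,women,bmi,21.9
2016,men,sbp,128.9
2016,men,sg,
2016,men,tg,
2016,men,hdl,56.9
2016,men,bmi,23.8
2016,women,sbp,119.7
2016,women,sg,
2016,women,tg,
2016,women,hdl,69.1
2016,women,bmi,22.1
2017,men,sbp,128.1
2017,men,sg,95.4
2017,men,tg,165.5
2017,men,hdl,56.2
2017,men,bmi,23.9
2017,women,sbp,120.5
2017,women,sg,93.7
2017,women,tg,111.7
2017,women,hdl,68.7
2017,women,bmi,22.1
2018,men,sbp,128.1
2018,men,sg,98.4
2018,men,tg,161.7
2018,men,hdl,58.4
2018,men,bmi,23.8
2018,women,sbp,119.8
2018,women,sg,95.3
2018,women,tg,114.8
2018,women,hdl,69.4
2018,women,bmi,22.0
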