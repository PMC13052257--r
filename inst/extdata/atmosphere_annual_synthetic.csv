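year,ca,d13ca
1700,276,-6.4
1701,276,-6.4001
1702,276,-6.4002
1703,276,-6.4003
1704,276.001,-6.4004
1705,276.001,-6.4005
1706,276.002,-6.4006
1707,276.003,-6.4008
1708,276.004,-6.401
1709,276.006,-6.4011
1710,276.008,-6.4013
1711,276.011,-6.4016
1712,276.014,-6.4018
1713,276.018,-6.402
1714,276.022,-6.4023
1715,276.027,-6.4025
1716,276.033,-6.4028
1717,276.039,-6.4031
1718,276.047,-6.4034
1719,276.055,-6.4037
1720,276.064,-6.404
1721,276.074,-6.4044
1722,276.085,-6.4047
1723,276.097,-6.4051
1724,276.111,-6.4055
1725,276.125,-6.4058
1726,276.141,-6.4063
1727,276.157,-6.4067
1728,276.176,-6.4071
1729,276.195,-6.4076
1730,276.216,-6.408
1731,276.238,-6.4085
1732,276.262,-6.409
1733,276.287,-6.4095
1734,276.314,-6.41
1735,276.343,-6.4105
1736,276.373,-6.4111
1737,276.405,-6.4116
1738,276.439,-6.4122
1739,276.475,-6.4128
1740,276.512,-6.4133
1741,276.551,-6.4139
1742,276.593,-6.4146
1743,276.636,-6.4152
1744,276.681,-6.4158
1745,276.729,-6.4165
1746,276.779,-6.4172
1747,276.831,-6.4179
1748,276.885,-6.4186
1749,276.941,-6.4193
1750,277,-6.42
1751,277.063,-6.4207
1752,277.133,-6.4215
1753,277.209,-6.4223
1754,277.29,-6.423
1755,277.377,-6.4238
1756,277.47,-6.4246
1757,277.567,-6.4254
1758,277.67,-6.4262
1759,277.777,-6.427
1760,277.888,-6.4279
1761,278.003,-6.4287
1762,278.123,-6.4296
1763,278.246,-6.4304
1764,278.372,-6.4313
1765,278.501,-6.4321
1766,278.633,-6.433
1767,278.768,-6.4338
1768,278.904,-6.4347
1769,279.043,-6.4356
1770,279.184,-6.4365
1771,279.327,-6.4373
1772,279.47,-6.4382
1773,279.615,-6.4391
1774,279.761,-6.4399
1775,279.907,-6.4408
1776,280.053,-6.4417
1777,280.199,-6.4425
1778,280.346,-6.4434
1779,280.491,-6.4442
1780,280.636,-6.4451
1781,280.78,-6.4459
1782,280.923,-6.4468
1783,281.065,-6.4476
1784,281.204,-6.4484
1785,281.342,-6.4492
1786,281.478,-6.45
1787,281.611,-6.4508
1788,281.741,-6.4516
1789,281.868,-6.4524
1790,281.992,-6.4531
1791,282.113,-6.4539
1792,282.23,-6.4546
1793,282.343,-6.4554
1794,282.451,-6.4561
1795,282.555,-6.4568
1796,282.655,-6.4574
1797,282.749,-6.4581
1798,282.838,-6.4588
1799,282.922,-6.4594
1800,283,-6.46
1801,283.073,-6.4606
1802,283.142,-6.4612
1803,283.208,-6.4617
1804,283.27,-6.4623
1805,283.329,-6.4628
1806,283.385,-6.4634
1807,283.438,-6.4639
1808,283.488,-6.4645
1809,283.536,-6.465
1810,283.581,-6.4655
1811,283.624,-6.4661
1812,283.665,-6.4667
1813,283.705,-6.4672
1814,283.743,-6.4678
1815,283.779,-6.4684
1816,283.814,-6.469
1817,283.847,-6.4697
1818,283.88,-6.4704
1819,283.912,-6.471
1820,283.944,-6.4718
1821,283.975,-6.4725
1822,284.006,-6.4733
1823,284.037,-6.4742
1824,284.068,-6.475
1825,284.099,-6.4759
1826,284.131,-6.4769
1827,284.163,-6.4779
1828,284.197,-6.479
1829,284.231,-6.4801
1830,284.266,-6.4812
1831,284.303,-6.4825
1832,284.342,-6.4837
1833,284.382,-6.4851
1834,284.424,-6.4865
1835,284.468,-6.488
1836,284.514,-6.4895
1837,284.563,-6.4911
1838,284.614,-6.4928
1839,284.669,-6.4946
1840,284.726,-6.4965
1841,284.786,-6.4984
1842,284.85,-6.5004
1843,284.917,-6.5025
1844,284.988,-6.5047
1845,285.062,-6.507
1846,285.141,-6.5094
1847,285.224,-6.5119
1848,285.311,-6.5145
1849,285.403,-6.5172
1850,285.5,-6.52
1851,285.602,-6.5229
1852,285.708,-6.5259
1853,285.819,-6.529
1854,285.935,-6.5323
1855,286.056,-6.5356
1856,286.182,-6.539
1857,286.313,-6.5425
1858,286.448,-6.5461
1859,286.588,-6.5498
1860,286.732,-6.5536
1861,286.881,-6.5574
1862,287.035,-6.5614
1863,287.193,-6.5654
1864,287.356,-6.5695
1865,287.524,-6.5737
1866,287.696,-6.5779
1867,287.872,-6.5823
1868,288.053,-6.5867
1869,288.238,-6.5911
1870,288.428,-6.5956
1871,288.621,-6.6002
1872,288.82,-6.6049
1873,289.022,-6.6096
1874,289.229,-6.6144
1875,289.44,-6.6192
1876,289.655,-6.624
1877,289.874,-6.6289
1878,290.098,-6.6339
1879,290.325,-6.6389
1880,290.557,-6.644
1881,290.792,-6.649
1882,291.032,-6.6542
1883,291.276,-6.6593
1884,291.523,-6.6645
1885,291.775,-6.6697
1886,292.03,-6.675
1887,292.29,-6.6802
1888,292.553,-6.6855
1889,292.82,-6.6908
1890,293.091,-6.6962
1891,293.365,-6.7015
1892,293.643,-6.7069
1893,293.925,-6.7123
1894,294.211,-6.7176
1895,294.5,-6.723
1896,294.793,-6.7284
1897,295.09,-6.7338
1898,295.39,-6.7392
1899,295.693,-6.7446
1900,296,-6.75
1901,296.31,-6.7554
1902,296.624,-6.7608
1903,296.942,-6.7661
1904,297.264,-6.7714
1905,297.589,-6.7767
1906,297.918,-6.782
1907,298.252,-6.7873
1908,298.589,-6.7925
1909,298.931,-6.7976
1910,299.277,-6.8027
1911,299.628,-6.8078
1912,299.983,-6.8128
1913,300.342,-6.8177
1914,300.707,-6.8225
1915,301.076,-6.8273
1916,301.451,-6.832
1917,301.83,-6.8367
1918,302.215,-6.8412
1919,302.605,-6.8457
1920,303,-6.85
1921,303.4,-6.8543
1922,303.805,-6.8584
1923,304.213,-6.8626
1924,304.623,-6.8667
1925,305.034,-6.8708
1926,305.444,-6.8749
1927,305.853,-6.8791
1928,306.259,-6.8833
1929,306.661,-6.8877
1930,307.059,-6.8922
1931,307.45,-6.8968
1932,307.834,-6.9017
1933,308.209,-6.9067
1934,308.574,-6.912
1935,308.929,-6.9175
1936,309.272,-6.9234
1937,309.602,-6.9295
1938,309.917,-6.936
1939,310.217,-6.9428
1940,310.5,-6.95
1941,310.766,-6.9576
1942,311.018,-6.9657
1943,311.259,-6.9742
1944,311.492,-6.9831
1945,311.721,-6.9926
1946,311.95,-7.0025
1947,312.181,-7.0129
1948,312.419,-7.0238
1949,312.666,-7.0353
1950,312.926,-7.0473
1951,313.203,-7.0598
1952,313.499,-7.0729
1953,313.819,-7.0866
1954,314.166,-7.1009
1955,314.543,-7.1158
1956,314.953,-7.1313
1957,315.401,-7.1475
1958,315.889,-7.1643
1959,316.421,-7.1818
1960,317,-7.2
1961,317.629,-7.2188
1962,318.309,-7.2383
1963,319.039,-7.2581
1964,319.818,-7.2784
1965,320.645,-7.2988
1966,321.521,-7.3193
1967,322.445,-7.3398
1968,323.417,-7.3602
1969,324.435,-7.3803
1970,325.5,-7.4
1971,326.611,-7.4193
1972,327.766,-7.4382
1973,328.966,-7.457
1974,330.208,-7.4758
1975,331.492,-7.4949
1976,332.817,-7.5144
1977,334.181,-7.5345
1978,335.583,-7.5553
1979,337.023,-7.5771
1980,338.5,-7.6
1981,340.011,-7.6242
1982,341.55,-7.6493
1983,343.109,-7.6752
1984,344.682,-7.7014
1985,346.262,-7.7278
1986,347.841,-7.7539
1987,349.411,-7.7795
1988,350.966,-7.8042
1989,352.498,-7.8278
1990,354,-7.85
1991,355.468,-7.8705
1992,356.911,-7.8897
1993,358.341,-7.9081
1994,359.77,-7.926
1995,361.21,-7.944
1996,362.673,-7.9624
1997,364.172,-7.9818
1998,365.718,-8.0025
1999,367.323,-8.0251
2000,369,-8.05
2001,370.758,-8.0774
2002,372.594,-8.107
2003,374.503,-8.1381
2004,376.481,-8.1702
2005,378.523,-8.2027
2006,380.622,-8.2349
2007,382.775,-8.2663
2008,384.975,-8.2964
2009,387.219,-8.3245
2010,389.5,-8.35
2011,391.814,-8.3726
2012,394.154,-8.3931
2013,396.513,-8.4124
2014,398.885,-8.4316
2015,401.262,-8.4517
2016,403.639,-8.4736
2017,406.007,-8.4984
2018,408.362,-8.527
2019,410.695,-8.5606
2020,413,-8.6
2021,415.271,-8.6462
2022,417.5,-8.7
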