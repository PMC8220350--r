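city,country,lat,lon
Boston,USA,42.36,-71.06
Ehime,Japan,33.84,132.77
Valencia,Spain,39.47,-0.38
South Carolina,USA,33.84,-81.03
Toulon,France,43.12,5.93
Nyons,France,44.36,5.14
Grenoble,France,45.19,5.72
Tarentaise,France,45.37,6.53
Van,Turkey,38.50,43.38
Southampton,UK,50.91,-1.40
Wellington,New Zealand,-41.25,174.78
Vasteras,Sweden,59.61,16.55
Copenhagen,Denmark,55.68,12.57
Athens,Greece,37.98,23.73
Edirne,Turkey,41.15,26.56
Milan,Italy,45.46,9.19
Ioannina,Greece,39.77,20.85
Manchester,UK,53.48,-2.24
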