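# Medical-care component of the US Consumer Price Index, annual averages
# (BLS series CUUR0000SAM, 1982-84 = 100). Used to convert nominal paid
# amounts to 2021 US dollars: cost_2021 = cost * index[2021] / index[year].
cpi_medical:
  2014: 435.292
  2015: 446.752
  2016: 463.675
  2017: 475.327
  2018: 484.714
  2019: 498.214
  2020: 518.076
  2021: 521.482
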