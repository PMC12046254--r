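country,date,value
IT,2020-03-01,2
IT,2020-03-02,1
IT,2020-03-03,4
IT,2020-03-04,6
IT,2020-03-05,9
IT,2020-03-06,14
IT,2020-03-07,21
IT,2020-03-08,30
IT,2020-03-09,42
IT,2020-03-10,55
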