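country,date,value
IT,2020-03-01,1.2
IT,2020-03-02,1.5
IT,2020-03-03,2.1
IT,2020-03-04,3.8
IT,2020-03-05,6.4
IT,2020-03-06,9.9
IT,2020-03-07,14.2
IT,2020-03-08,18.8
IT,2020-03-09,22.5
IT,2020-03-10,25.1
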