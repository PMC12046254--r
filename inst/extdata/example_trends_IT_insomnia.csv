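Category: All categories

Week,insomnia: (Italy)
2015-03-01,49
2015-03-08,52
2015-03-15,50
2015-03-22,59
2015-03-29,56
2015-04-05,53
2015-04-12,57
2015-04-19,59
2015-04-26,59
2015-05-03,57
2015-05-10,62
2015-05-17,59
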