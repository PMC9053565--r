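# marker phrase <TAB> qualifier (over|under); matched immediately before a number
más de	over
por encima de	over
menos de	under
por debajo de	under
casi	under
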