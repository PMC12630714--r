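category,n_events,casualties
battle,71323,317795
violence_against_civilians,70726,182875
explosion_remote,21852,59284
strategic_development,19027,533
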