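"site","arm","n","events"
"all","epidex",199,34
"all","epi",199,47
"all","dex",199,51
"all","placebo",200,53
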