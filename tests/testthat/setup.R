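# expanded merged network built once and shared across test files
merged_model <- build_merged_model()
merged_net <- expand_rules(merged_model)
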