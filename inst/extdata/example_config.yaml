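terminology: inst/extdata/terminology.tsv
form: inst/extdata/chd_form.json
threshold: 0.8
conflict_policy: last_mention_wins
seed: 1
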