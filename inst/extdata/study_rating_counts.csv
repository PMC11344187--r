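quantity,count
rated_boards,5818
rater_agreements,4829
retained_provaccination,1283
retained_hesitant,1322
retained_antivaccination,387
excluded_neutral_irrelevant,2826
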