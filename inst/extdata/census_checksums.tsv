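file	md5
census_family_sizes.tsv	bb68ed934458c0aab1284edf3b70505d
census_missing_fhco.tsv	137f72e6c0c9ee7c89c0558ed47fe842
census_sensitivity.tsv	b8faf4c1ea3f8635723dff9fba080e6b
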