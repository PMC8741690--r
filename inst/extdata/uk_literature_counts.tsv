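cohort	n_cases	n_cohort	n_recessive	description
uk_systematic	20	808	0	Systematic screening of a UK paediatric diabetes clinic population (literature counts, not data)
uk_routine_referrals	102	NA	2	Routine UK diagnostic referrals diagnosed 0.5-20 years (literature counts, not data)
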