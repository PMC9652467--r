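# Published ASP category counts from three longevity-intervention
# deep-phenotyping studies in mice: a growth-hormone-releasing-hormone
# receptor loss-of-function dwarf mutant (ghrhr_lit), a hypomorphic mTOR
# knock-in mutant (mtor_ki) and intermittent fasting / every-other-day
# feeding (if_eod).  Countered ASPs are split into baseline versus
# rate-or-combined model counts separately for the interaction route and
# the effect-size (z-test) route.
study	n_asp	unaffected	accentuated	unevaluable	countered_baseline_interaction	countered_rate_interaction	countered_baseline_effectsize	countered_rate_effectsize
ghrhr_lit	96	35	18	5	28	10	33	5
mtor_ki	117	42	15	4	37	19	45	11
if_eod	102	48	11	1	28	14	31	11
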