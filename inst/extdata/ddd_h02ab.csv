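substance,atc_code,ddd_mg,route
betamethasone,H02AB01,1.5,oral
dexamethasone,H02AB02,1.5,oral
methylprednisolone,H02AB04,7.5,oral
prednisolone,H02AB06,10,oral
prednisone,H02AB07,10,oral
triamcinolone,H02AB08,7.5,oral
hydrocortisone,H02AB09,30,oral
cortisone,H02AB10,37.5,oral
deflazacort,H02AB13,15,oral
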