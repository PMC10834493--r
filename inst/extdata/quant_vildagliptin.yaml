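# External-standard quantitation constants for a 50 mg immediate-release
# tablet run: 12.84 mg standard -> 25 mL stock, 2 mL -> 20 mL working
# solution; 1000 mL medium, 10 mL aliquot withdrawn per sampling.
std_mass_mg: 12.84
std_stock_vol_ml: 25
std_aliquot_ml: 2
std_final_vol_ml: 20
std_purity_frac: 1.0
label_claim_mg: 50
medium_vol_ml: 1000
withdrawal_vol_ml: 10
replacement: replaced
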