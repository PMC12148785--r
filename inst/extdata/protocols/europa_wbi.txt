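# Whole-breast irradiation arm: 40.05 Gy in 15 fractions. This schedule
# overlaps the moderate-hypofractionation window of the RTOG-style
# protocol, so it ships WITHOUT an automatic selection rule (schedule =
# none) and is applied only via explicit protocol override. Site-editable.
name = EUROPA_WBI
schedule = none
min_ptvs = 1
max_ptvs = 2

PTV_BREAST | V38Gy[%] | GE | 90 | 95 | std | PTV            # [trial] 95% isodose coverage
PTV_BREAST | D2%[Gy] | LE | 44.1 | - | std | PTV            # [trial] hotspot <=110%
LUNG_IPSI | V16Gy[%] | LE | 20 | 15 | std | MAIN_OAR        # [trial]
HEART | Dmean[Gy] | LE | 4 | 3.2 | std | MAIN_OAR           # [trial]
BREAST_CONTRA | Dmean[Gy] | LE | 1 | - | extra | MAIN_OAR   # [site]
LUNG_CONTRA | V4Gy[%] | LE | 15 | 10 | std | MAIN_OAR       # [trial]
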