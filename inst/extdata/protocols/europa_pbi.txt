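# Partial-breast irradiation arm of the elderly whole- vs partial-breast
# trial: 30 Gy in 5 daily fractions. The 6.0-6.4 Gy/fraction window keeps
# this schedule disjoint from the 28.5 Gy / 5 once-weekly schedule.
# [trial]-tagged values follow the trial planning guidance; site-editable.
name = EUROPA_PBI
schedule = 5 x 6.0-6.4
min_ptvs = 1
max_ptvs = 1

PTV_BREAST | V28.5Gy[%] | GE | 90 | 95 | std | PTV          # [trial] 95% isodose coverage
PTV_BREAST | D2%[Gy] | LE | 32.1 | - | std | PTV            # [trial] hotspot <=107%
LUNG_IPSI | V9Gy[%] | LE | 10 | - | std | MAIN_OAR          # [trial]
HEART | Dmean[Gy] | LE | 1.5 | - | std | MAIN_OAR           # [trial]
BREAST_CONTRA | Dmean[Gy] | LE | 1 | - | std | MAIN_OAR     # [trial]
LUNG_CONTRA | V3Gy[%] | LE | 10 | - | extra | MAIN_OAR      # [site]
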