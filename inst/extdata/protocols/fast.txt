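# FAST whole-breast once-weekly hypofractionation: 28.5 Gy in 5 weekly
# fractions. The nominal 5.7 Gy/fraction sits inside the 5.5-5.9 selection
# window (kept below 6.0 so the partial-breast 30 Gy / 5 schedule stays
# disjoint). [trial] values follow the published trial guidance scaled to
# the prescription; [site] entries are local additions. Site-editable.
name = FAST
schedule = 5 x 5.5-5.9
min_ptvs = 1
max_ptvs = 2

PTV_BREAST | V27.1Gy[%] | GE | 90 | 95 | std | PTV          # [trial] 95% isodose coverage
PTV_BREAST | D2%[Gy] | LE | 30.5 | - | std | PTV            # [trial] hotspot <=107%
LUNG_IPSI | V8.6Gy[%] | LE | 15 | - | std | MAIN_OAR        # [trial] 30% isodose
HEART | V14.3Gy[%] | LE | 5 | - | std | MAIN_OAR            # [trial] 50% isodose
HEART | V8.6Gy[%] | LE | 30 | - | std | MAIN_OAR            # [trial] 30% isodose
LUNG_CONTRA | V3Gy[%] | LE | 10 | - | extra | MAIN_OAR      # [site]
HEART | Dmean[Gy] | LE | 2 | - | extra | MAIN_OAR           # [site]
BREAST_CONTRA | Dmean[Gy] | LE | 1 | - | extra | MAIN_OAR   # [site]
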