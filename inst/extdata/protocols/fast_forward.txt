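# FAST-FORWARD whole-breast ultra-hypofractionation: 26 Gy in 5 daily
# fractions. Constraint lines: role | metric | comparator | mandatory |
# optimal | tier | group. Values marked [trial] follow the published trial
# planning guidance; [site] entries are conservative local additions and,
# like everything here, site-editable configuration.
name = FAST_FORWARD
schedule = 5 x 5.0-5.4
min_ptvs = 1
max_ptvs = 2

PTV_BREAST | V24.7Gy[%] | GE | 90 | 95 | std | PTV          # [trial] 95% isodose coverage
PTV_BREAST | D2%[Gy] | LE | 28.6 | 27.8 | std | PTV         # [trial] hotspot <=110% / opt 107%
LUNG_IPSI | V8Gy[%] | LE | 15 | - | std | MAIN_OAR          # [trial] ipsilateral lung
HEART | V1.5Gy[%] | LE | 30 | - | std | MAIN_OAR            # [trial]
HEART | V7Gy[%] | LE | 5 | - | std | MAIN_OAR               # [trial]
LUNG_IPSI | V16Gy[%] | LE | 20 | - | extra | MAIN_OAR       # [site] cross-protocol lung check
LUNG_CONTRA | V3Gy[%] | LE | 10 | - | extra | MAIN_OAR      # [site] suggested ceiling
HEART | Dmean[Gy] | LE | 2 | - | extra | MAIN_OAR           # [site] suggested ceiling
BREAST_CONTRA | Dmean[Gy] | LE | 1 | - | extra | MAIN_OAR   # [site]
ESOPHAGUS | Dmean[Gy] | LE | 3 | - | extra | OTHER_OAR      # [site]
STOMACH | Dmean[Gy] | LE | 2 | - | extra | OTHER_OAR        # [site]
LIVER | Dmean[Gy] | LE | 2 | - | extra | OTHER_OAR          # [site]
THYROID | Dmean[Gy] | LE | 3 | - | extra | OTHER_OAR        # [site]
SKIN | D2cc[Gy] | LE | 27 | - | extra | OTHER_OAR           # [site]
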