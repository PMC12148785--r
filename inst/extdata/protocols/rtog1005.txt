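# RTOG 1005-style whole-breast schedules: moderate hypofractionation
# (15-16 fractions of 2.5-2.9 Gy) or conventional fractionation (23-25
# fractions of 1.8-2.1 Gy). Constraints are written for the 40 Gy / 15
# nominal prescription; [protocol] values follow the trial planning
# document (acceptable / preferred pairs drive the yellow tier), [site]
# entries are local additions. Site-editable.
name = RTOG1005
schedule = 15-16 x 2.5-2.9
schedule = 23-25 x 1.8-2.1
min_ptvs = 1
max_ptvs = 3

PTV_BREAST | V38Gy[%] | GE | 90 | 95 | std | PTV            # [protocol] 95% isodose coverage
PTV_BREAST | D2%[Gy] | LE | 44 | 43.2 | std | PTV           # [protocol] hotspot 110% / 108%
LUNG_IPSI | V16Gy[%] | LE | 20 | 15 | std | MAIN_OAR        # [protocol] acceptable / preferred
LUNG_CONTRA | V4Gy[%] | LE | 15 | 10 | std | MAIN_OAR       # [protocol]
HEART | Dmean[Gy] | LE | 4 | 3.2 | std | MAIN_OAR           # [protocol]
HEART | V16Gy[%] | LE | 5 | - | std | MAIN_OAR              # [protocol]
BREAST_CONTRA | Dmax[Gy] | LE | 4 | 2.4 | std | MAIN_OAR    # [protocol]
LAD | Dmax[Gy] | LE | 10 | - | extra | MAIN_OAR             # [site] coronary sparing
ESOPHAGUS | Dmean[Gy] | LE | 5 | - | extra | OTHER_OAR      # [site]
SKIN | D2cc[Gy] | LE | 40 | - | extra | OTHER_OAR           # [site]
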