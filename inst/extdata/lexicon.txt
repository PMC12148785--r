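# Structure-name lexicon: ROLE: token1, token2, ...
# Tokens match case-insensitively on word-ish boundaries ("dx" matches
# "Polmone DX" but not "index"). English + Italian defaults; edit freely.
# LEFT / RIGHT list laterality tokens; LUNG / BREAST are side-neutral organ
# tokens used together with laterality for ipsi/contra resolution.

LEFT: left, lt, sx, sin, sinistro, sinistra, l
RIGHT: right, rt, dx, des, destro, destra, r

PTV_BREAST: ptv breast, ptv_breast, ptv-breast, ptv mammella, ptv_mammella, breast ptv, ptv wb, ptv chw, ptv chestwall, ptv parete, ptv
PTV_BOOST: boost, ptv_boost, letto tumorale
PTV_NODES: nodes, node, ptv_nodes, linfonodi, lymph, ln, ptv n
LUNG: lung, polmone, polm
HEART: heart, cuore
LAD: lad, left coronary, coronaria, iva, descending artery
BREAST_CONTRA: breast, mammella, mamm
ESOPHAGUS: esophagus, oesophagus, esofago
STOMACH: stomach, stomaco
LIVER: liver, fegato
THYROID: thyroid, tiroide
SKIN: skin, cute, pelle
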