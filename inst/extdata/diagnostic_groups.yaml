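# Curated diagnostic groups for pediatric continuity-clinic experience
# tracking: 22 groups, each a list of ICD-10 code tokens (exact codes,
# ".xx" category wildcards, or ranges). Tokens are reproduced verbatim from
# the source curation, including typographic hyphens inside some ranges.
version: "pediatric-continuity-clinic-v1"
groups:
  - name: "Well check"
    codes: ["Z00.129", "Z00.121"]
    notes: ~
  - name: "Anemia"
    codes: ["D50-D64"]
    notes: ~
  - name: "Constipation"
    codes: ["K59.xx"]
    notes: ~
  - name: "Vomiting/diarrhea"
    codes: ["R11.1", "R11.2", "R19.7", "A09"]
    notes: ~
  - name: "Underweight/failure to thrive"
    codes: ["R62.51"]
    notes: ~
  - name: "Gait problem/limp"
    codes: ["R26.xx"]
    notes: "In toeing, limp, genu varus, genu valgus"
  - name: "Genitourinary concerns"
    codes: ["N43.xx", "N47.xx", "N48.xx", "N90.89", "K40.xx", "K41.xx",
            "Q53.xx", "Q54.xx", "Q55.xx"]
    notes: "Hydroceles, phimosis, labial adhesions, hernias"
  - name: "Overweight/obesity, increased BMI"
    codes: ["Z68.51-Z68.54", "E66.3", "E66.9", "E66.09"]
    notes: ~
  - name: "Sexually transmitted infections"
    codes: ["A50.0-A64", "Z11.3-Z11.9"]
    notes: "Screening and management"
  - name: "Asthma"
    codes: ["J45.xx"]
    notes: ~
  - name: "Eczema"
    codes: ["L30.8", "L30.9", "L20.9", "L20.82", "L20.83", "L20.84", "L21.1"]
    notes: ~
  - name: "Heart murmurs"
    codes: ["R01.xx", "I35.8", "Q21.xx-Q24.xx"]
    notes: "Functional and pathologic"
  - name: "Ear infections"
    codes: ["H65.xx-H66.xx", "H60.xx"]
    notes: "Otitis media and variants, otitis externa"
  - name: "Urinary tract infection"
    codes: ["N10", "N30.xx", "N39"]
    notes: ~
  - name: "Developmental delay"
    codes: ["F80.xx", "F82", "F88", "F89", "R62.50"]
    notes: ~
  - name: "Behavioral/ADHD"
    codes: ["F90.0‐90.2", "F90.8‐90.9", "F91.0‐91.3", "F91.8‐91.9", "F93.0",
            "F93.8‐94.2", "F94.8‐94.9", "F95", "F98", "F30-39.9999",
            "F40-48.9999"]
    notes: "Depression, anxiety, ADHD with all variants"
  - name: "Young women’s health"
    codes: ["Z30.xx", "N92.6", "N93.9", "N94.3‐97"]
    notes: "Contraception, menstrual concerns"
  - name: "Headache"
    codes: ["G43.xx-G44.xx", "R51"]
    notes: ~
  - name: "Autism spectrum disorder"
    codes: ["F84.xx"]
    notes: ~
  - name: "Genetic and chromosomal disorders"
    codes: ["Q90-Q99.xx"]
    notes: ~
  - name: "Specific congenital nongenetic disorders"
    codes: ["Q35.xx-37.xx", "Q05.xx"]
    notes: "Spina bifida and variants, cleft lip and palate"
  - name: "Vaccine hesitancy"
    codes: ["Z28.xx"]
    notes: ~
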