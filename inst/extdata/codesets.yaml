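# Default codeset configuration for fncohort.
#
# These are PLACEHOLDER code lists in ICD-10-CM / HCPCS / pseudo-NDC style.
# Real deployments must replace them with the organisation's validated lists;
# every clinical rule in the package reads codes only from this registry, so
# swapping this file changes behaviour with no code change.
#
# Pharmacy drug codes use readable "ndc-<drug>-<strength>" placeholders rather
# than real 11-digit NDCs.

codesets:
  neutropenia_dx:
    system: ICD10CM
    codes: [D70.0, D70.1, D70.2, D70.3, D70.8, D70.9]
  fever_dx:
    system: ICD10CM
    codes: [R50.81, R50.82, R50.9]
  bacterial_infection_dx:
    system: ICD10CM
    codes: [A41.9, A41.50, A49.9, J15.9, J18.9, N39.0, L03.90, A04.7]
  fungal_infection_dx:
    system: ICD10CM
    codes: [B37.0, B37.7, B44.9, B49, B37.9]
  covid_dx:
    system: ICD10CM
    codes: [U07.1]
  excluded_heme_dx:          # ALL / AML / CML / MDS
    system: ICD10CM
    codes: [C91.00, C91.01, C91.02, C92.00, C92.01, C92.02, C92.10, C92.11, C92.12,
            D46.9, D46.20, D46.21, D46.22, D46.4, D46.Z]
  bmt_sct_cart_proc:         # bone marrow / stem cell transplant, CAR-T
    system: HCPCS
    codes: ['38240', '38241', '38242', '0537T', '0538T', '0539T', '0540T', 'Q2041', 'Q2042']
  nccn_parenteral_antibiotic_proc:
    system: HCPCS
    codes: [J0690, J0696, J0697, J0744, J1956, J2543]
  gcsf_short:                # filgrastim-class
    system: HCPCS/NDC
    codes: [J1442, J1447, Q5101, Q5110, ndc-filgrastim-300, ndc-filgrastim-480]
  gcsf_long:                 # pegfilgrastim-class
    system: HCPCS/NDC
    codes: [J2505, Q5108, Q5111, Q5120, Q5122, ndc-pegfilgrastim-6]
  abx_ciprofloxacin:
    system: NDC
    codes: [ndc-ciprofloxacin-250, ndc-ciprofloxacin-500, ndc-ciprofloxacin-750]
  abx_amoxicillin_clavulanate:
    system: NDC
    codes: [ndc-amoxclav-500, ndc-amoxclav-875]
  abx_clindamycin:
    system: NDC
    codes: [ndc-clindamycin-150, ndc-clindamycin-300]
  abx_levofloxacin:
    system: NDC
    codes: [ndc-levofloxacin-500, ndc-levofloxacin-750]
  abx_moxifloxacin:
    system: NDC
    codes: [ndc-moxifloxacin-400]
  antibacterial:
    system: NDC
    codes: [ndc-ciprofloxacin-250, ndc-ciprofloxacin-500, ndc-ciprofloxacin-750,
            ndc-amoxclav-500, ndc-amoxclav-875, ndc-clindamycin-150, ndc-clindamycin-300,
            ndc-levofloxacin-500, ndc-levofloxacin-750, ndc-moxifloxacin-400,
            ndc-azithromycin-250, ndc-cephalexin-500, ndc-tmpsmx-800]
  antifungal:
    system: NDC
    codes: [ndc-fluconazole-150, ndc-fluconazole-200, ndc-posaconazole-100]
  antiviral:
    system: NDC
    codes: [ndc-acyclovir-400, ndc-valacyclovir-500, ndc-oseltamivir-75]
  bone_met_dx:
    system: ICD10CM
    codes: [C79.51, C79.52]
  surgery_proc:
    system: HCPCS
    codes: ['19301', '19303', '32480', '44140', '44204', '60220', '55840', '58150']
  radiation_codes:
    system: HCPCS/ICD10CM
    codes: ['77385', '77386', '77402', '77407', '77412', '77417', Z51.0]
  liver_dysfunction_dx:      # severe liver dysfunction
    system: ICD10CM
    codes: [K70.40, K70.41, K72.10, K72.90, K72.91, K76.6, K76.7]
  kidney_dysfunction_dx:
    system: ICD10CM
    codes: [N17.9, N18.4, N18.5, N18.6]
  nhl_dx:
    system: ICD10CM
    codes: [C82.90, C83.30, C83.90, C84.40, C85.90]
  cll_dx:
    system: ICD10CM
    codes: [C91.10, C91.11, C91.12]
  other_heme_dx:             # e.g. Hodgkin lymphoma, histiocytosis, mastocytosis
    system: ICD10CM
    codes: [C81.90, C81.10, C96.0, C96.20, C96.9, C94.6]
  breast_dx:
    system: ICD10CM
    codes: [C50.911, C50.912, C50.919]
  lung_dx:
    system: ICD10CM
    codes: [C34.90, C34.91, C34.92]
  colorectal_dx:
    system: ICD10CM
    codes: [C18.9, C19, C20]
  prostate_dx:
    system: ICD10CM
    codes: [C61]
  other_solid_dx:
    system: ICD10CM
    codes: [C16.9, C25.9, C56.9, C67.9, C71.9, C73, C80.1]

# Chemotherapy / biologic drug dictionary: drug name -> claim codes
# (HCPCS J-codes for administered drugs, pseudo-NDCs for oral fills).
chemo_drugs:
  doxorubicin:      [J9000]
  cyclophosphamide: [J9070, ndc-cyclophosphamide-50]
  docetaxel:        [J9171]
  paclitaxel:       [J9267]
  carboplatin:      [J9045]
  cisplatin:        [J9060]
  topotecan:        [J9351, ndc-topotecan-1]
  etoposide:        [J9181, ndc-etoposide-50]
  vincristine:      [J9370]
  rituximab:        [J9312]
  fluorouracil:     [J9190]
  oxaliplatin:      [J9263]
  irinotecan:       [J9206]
  gemcitabine:      [J9201]
  pembrolizumab:    [J9271]
  capecitabine:     [ndc-capecitabine-500]

# Regimen dictionary with NCCN-style FN-risk labels. A regimen matches an
# episode when every listed drug appears in the chemotherapy treatment period;
# optional conditions:
#   requires_dx — codeset that must appear in the pre-episode period
#                 (context-dependent drugs such as docetaxel / topotecan);
#   min_cycles  — minimum number of distinct administration dates of the
#                 regimen's drugs over the 180 days before index
#                 (dose-dense doxorubicin/cyclophosphamide).
# Episodes whose drugs match no configured regimen are low/undefined risk.
regimens:
  - name: TAC
    drugs: [docetaxel, doxorubicin, cyclophosphamide]
    risk: high
  - name: R-CHOP
    drugs: [rituximab, cyclophosphamide, doxorubicin, vincristine]
    risk: high
  - name: dose-dense AC
    drugs: [doxorubicin, cyclophosphamide]
    risk: high
    min_cycles: 4
  - name: docetaxel (breast)
    drugs: [docetaxel]
    risk: high
    requires_dx: breast_dx
  - name: topotecan (lung)
    drugs: [topotecan]
    risk: high
    requires_dx: lung_dx
  - name: AC
    drugs: [doxorubicin, cyclophosphamide]
    risk: intermediate
  - name: CHOP
    drugs: [cyclophosphamide, doxorubicin, vincristine]
    risk: intermediate
  - name: carboplatin-paclitaxel
    drugs: [carboplatin, paclitaxel]
    risk: intermediate
  - name: FOLFIRI
    drugs: [fluorouracil, irinotecan]
    risk: intermediate
  - name: etoposide-cisplatin
    drugs: [etoposide, cisplatin]
    risk: intermediate

# Oral outpatient antibiotic rules satisfying the NCCN-recommended list:
# each rule is a set of drug groups that must ALL have a same-day pharmacy fill.
oral_antibiotic_rules:
  - [abx_ciprofloxacin, abx_amoxicillin_clavulanate]
  - [abx_ciprofloxacin, abx_clindamycin]
  - [abx_levofloxacin]
  - [abx_moxifloxacin]

# NCI Charlson comorbidity index: condition -> weight and diagnosis codes.
# Weights are the published NCI comorbidity-index weights (non-integer);
# replace alongside the code lists for a different index.
cci_conditions:
  - {condition: acute_mi,            weight: 0.12624, codes: [I21.9, I22.9]}
  - {condition: history_mi,          weight: 0.07999, codes: [I25.2]}
  - {condition: chf,                 weight: 0.64441, codes: [I50.9, I50.22, I50.32]}
  - {condition: pvd,                 weight: 0.26232, codes: [I73.9, I70.209]}
  - {condition: cvd,                 weight: 0.27868, codes: [I63.9, G45.9, I67.9]}
  - {condition: copd,                weight: 0.52487, codes: [J44.9, J44.1, J43.9]}
  - {condition: dementia,            weight: 0.72219, codes: [F03.90, G30.9]}
  - {condition: paralysis,           weight: 0.39882, codes: [G81.90, G82.20]}
  - {condition: diabetes,            weight: 0.29408, codes: [E11.9, E10.9]}
  - {condition: diabetes_sequelae,   weight: 0.63839, codes: [E11.22, E11.40, E10.21]}
  - {condition: renal_disease,       weight: 0.60638, codes: [N18.9, N19, I12.0]}
  - {condition: mild_liver_disease,  weight: 0.73803, codes: [K70.30, K73.9, K74.60]}
  - {condition: mod_sev_liver,       weight: 1.50302, codes: [K72.11, K76.81, I85.00]}
  - {condition: ulcer,               weight: 0.07506, codes: [K25.9, K26.9, K27.9]}
  - {condition: rheumatologic,       weight: 0.21905, codes: [M05.9, M06.9, M32.9]}
  - {condition: aids,                weight: 0.58362, codes: [B20]}
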