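# Default infection-category catalog.
#
# This is a reconstruction: the study that defined the numbered category
# system published the category names and their arrangement into four
# episode classes, but not the underlying ICD-10 code lists.  The prefixes
# below are an expert ICD-10 reading of each named category and are meant
# to be overridden with a site-specific file where an authoritative mapping
# exists.  Patterns are dot-free 3- or 4-character ICD-10 prefixes; the
# longest matching prefix wins, so e.g. J121 (RSV pneumonia) overrides the
# generic pneumonia prefix J12.
version: "default-1.0"
fever_threshold_c: 38.0
categories:
  - id: "1"
    name: "Fever"
    class: FEVER_MARKER
    patterns: [R50]
  - id: "2.1"
    name: "Common cold"
    class: RESPIRATORY
    patterns: [J00, J06]
  - id: "2.2"
    name: "Laryngitis and tracheitis"
    class: RESPIRATORY
    patterns: [J04, J05]
  - id: "2.3"
    name: "Influenza"
    class: RESPIRATORY
    patterns: [J09, J10, J11]
  - id: "2.4"
    name: "Enterovirus infection"
    class: RESPIRATORY
    patterns: [B341, B084, B085, B971]
  - id: "2.15"
    name: "Respiratory syncytial virus infection"
    class: RESPIRATORY
    patterns: [B974, J121, J205, J210]
  - id: "3"
    name: "Tonsillitis or streptococcal pharyngitis"
    class: RESPIRATORY
    patterns: [J02, J03]
  - id: "4"
    name: "Sinusitis"
    class: RESPIRATORY
    patterns: [J01]
  - id: "5"
    name: "Infections of middle ear and mastoid process"
    class: RESPIRATORY
    patterns: [H65, H66, H67, H70]
  - id: "6"
    name: "Bronchitis and lower respiratory infections"
    class: RESPIRATORY
    patterns: [J12, J13, J14, J15, J16, J17, J18, J20, J21, J22]
  - id: "11.1"
    name: "Conjunctivitis"
    class: RESPIRATORY
    patterns: [H10, B30]
  - id: "11.6b"
    name: "Other bacterial diseases, not elsewhere classified (respiratory tract)"
    class: RESPIRATORY
    site_tag: respiratory
    patterns: [A37, A481]
  - id: "7"
    name: "Infective gastroenteritis"
    class: GASTROINTESTINAL
    patterns: [A00, A01, A02, A03, A04, A05, A06, A07, A08, A09]
  - id: "8"
    name: "Gastroenteritis symptoms"
    class: GI_SYMPTOM
    patterns: [R11, R197, K529]
  - id: "2.5"
    name: "Chicken pox / varicella"
    class: OTHER
    patterns: [B01]
  - id: "2.6"
    name: "Zoster"
    class: OTHER
    patterns: [B02]
  - id: "2.7"
    name: "Erythema infectiosum"
    class: OTHER
    patterns: [B083]
  - id: "2.8"
    name: "Exanthema subitum"
    class: OTHER
    patterns: [B082]
  - id: "2.9"
    name: "Measles"
    class: OTHER
    patterns: [B05]
  - id: "2.10"
    name: "Mumps"
    class: OTHER
    patterns: [B26]
  - id: "2.11"
    name: "Rubella"
    class: OTHER
    patterns: [B06]
  - id: "2.12"
    name: "Herpes simplex virus infection"
    class: OTHER
    patterns: [B00]
  - id: "2.13"
    name: "Other viral rash"
    class: OTHER
    patterns: [B08, B09]
  - id: "2.14"
    name: "Infectious mononucleosis"
    class: OTHER
    patterns: [B27]
  - id: "2.16"
    name: "Viral infections of the central nervous system, not elsewhere classified"
    class: OTHER
    patterns: [A86, A87]
  - id: "2.17"
    name: "Other virus infections, not elsewhere classified"
    class: OTHER
    patterns: [B33, B34, B97]
  - id: "2.18"
    name: "Viral warts and molluscum"
    class: OTHER
    patterns: [B07, B081]
  - id: "9"
    name: "Parasites"
    class: OTHER
    patterns: [B80, B85, B86]
  - id: "10"
    name: "Mycoses"
    class: OTHER
    patterns: [B35, B36, B37]
  - id: "11.2"
    name: "Infections of external ear"
    class: OTHER
    patterns: [H60, H62]
  - id: "11.3"
    name: "Urinary tract infections"
    class: OTHER
    patterns: [N10, N30, N390]
  - id: "11.4"
    name: "Other genitourinary infections"
    class: OTHER
    patterns: [N34, N45, N76]
  - id: "11.5"
    name: "Bacterial skin diseases"
    class: OTHER
    patterns: [L00, L01, L02, L03, L08]
  - id: "11.6a"
    name: "Other bacterial diseases, not elsewhere classified (non-respiratory tract)"
    class: OTHER
    site_tag: non_respiratory
    patterns: [A46, A48, A49]
  - id: "11.7"
    name: "Diseases of oral cavity"
    class: OTHER
    patterns: [K04, K05, K12]
  - id: "11.8"
    name: "Lymphadenitis"
    class: OTHER
    patterns: [L04, I88]
  - id: "11.9"
    name: "Infections related to pregnancy, childbirth and puerperium"
    class: OTHER
    patterns: [O85, O86]
  - id: "11.10"
    name: "Perinatal/neonatal infections"
    class: OTHER
    patterns: [P36, P38, P39]
  - id: "11.11"
    name: "Other and unspecified infections"
    class: OTHER
    patterns: [B99]
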