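{
  "diagnoses": {
    "ed": ["607.84", "V41.7"],
    "ed_resolved": ["607.84R"],
    "low_libido": ["799.81"],
    "prostate_disease": ["600.00", "600.01"],
    "prostate_cancer": ["185"],
    "prostate_surgery": ["60.2"],
    "hypertension": ["401.9"],
    "diabetes": ["250.00"],
    "smoking": ["305.1"],
    "vascular_disease": ["440.9"],
    "depression": ["311"],
    "obesity": ["278.00"],
    "alcoholism": ["303.90"],
    "hsv": ["054.9"],
    "hiv": ["042"],
    "peyronie": ["607.85"],
    "alopecia": ["704.00"],
    "wellness": ["V70.0"]
  },
  "drugs": {
    "finasteride": {"class": "5ari", "approval": "1992-06-19"},
    "dutasteride": {"class": "5ari", "approval": "2001-11-20"},
    "sildenafil": {"class": "pde5i", "approval": "1998-03-27"},
    "ibuprofen": {"class": "nsaid", "approval": "1992-01-01"},
    "sertraline": {"class": "ssri", "approval": "1992-01-01"},
    "hydrochlorothiazide": {"class": "diuretic", "approval": "1992-01-01"},
    "acyclovir": {"class": "cyclovir", "approval": "1992-01-01"},
    "testosterone": {"class": "androgen", "approval": "1992-01-01"},
    "bicalutamide": {"class": "antiandrogen", "approval": "1995-10-04"}
  }
}
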