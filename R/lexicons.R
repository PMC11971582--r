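# Packaged phrase lists. Constraints the generator and the dictionary
# tagger rely on in the default ("easy") regime:
#   * the five entity lexicons are pairwise disjoint;
#   * no phrase is a word-boundary substring of another phrase in any
#     lexicon (so dictionary matches never truncate a longer phrase);
#   * within the Dx, Prior and Link lexicons no two phrases share a
#     word, so a linear bag-of-words model can represent "number of
#     distinct phrases present" exactly;
#   * phrases contain no sentence punctuation (periods delimit
#     sentences for evidence attachment).

DX_LEXICON <- c(
  "pneumonia", "cellulitis", "pyelonephritis", "cholecystitis", "pancreatitis",
  "appendicitis", "diverticulitis", "meningitis", "endocarditis", "pericarditis",
  "myocarditis", "hepatitis", "colitis", "gastritis", "esophagitis",
  "bronchitis", "sinusitis", "osteomyelitis", "epididymitis", "prostatitis",
  "gout", "sarcoidosis", "amyloidosis", "tuberculosis", "histoplasmosis",
  "aspergillosis", "nocardiosis", "babesiosis", "ehrlichiosis", "leptospirosis",
  "heart failure", "myocardial infarction", "pulmonary embolism",
  "aortic dissection", "atrial fibrillation", "ventricular tachycardia",
  "mitral regurgitation", "critical limb ischemia", "unstable angina",
  "cardiogenic shock", "septic arthritis", "bacterial peritonitis",
  "alcoholic cirrhosis", "biliary obstruction", "bowel perforation",
  "mesenteric thrombosis", "gastric ulcer", "variceal hemorrhage",
  "ischemic stroke", "subarachnoid bleed", "subdural hematoma",
  "status epilepticus", "wernicke encephalopathy", "guillain barre syndrome",
  "myasthenia gravis", "temporal arteritis", "multiple sclerosis",
  "transverse myelitis", "diabetic ketoacidosis", "thyroid storm",
  "adrenal insufficiency", "hypercalcemia", "myxedema coma",
  "pituitary apoplexy", "nephrolithiasis", "glomerulonephritis",
  "rhabdomyolysis", "obstructive uropathy", "interstitial nephritis",
  "tumor lysis", "hemolytic anemia", "aplastic crisis",
  "thrombotic microangiopathy", "neutropenic sepsis", "polycythemia vera",
  "essential thrombocythemia", "lung carcinoma", "lymphoma", "myeloma",
  "melanoma", "asthma exacerbation", "copd flare", "pneumothorax",
  "pleural empyema", "fibrosing alveolitis", "bronchiectasis",
  "fat embolus", "airway angioedema", "anaphylaxis", "serotonin excess",
  "malignant hyperthermia", "opioid overdose", "salicylate toxicity",
  "lithium poisoning", "digitalis intoxication", "serum sickness",
  "systemic lupus", "vasculitic purpura", "dermatomyositis", "scleroderma",
  "psoriatic arthropathy")

DC_LEXICON <- c(
  "cardiac", "infectious", "neurologic", "renal", "hepatic", "endocrine",
  "oncologic", "rheumatologic", "metabolic", "toxicologic", "psychiatric",
  "musculoskeletal")

PRIOR_LEXICON <- c(
  "most likely", "leading differential", "top consideration",
  "favored etiology", "highest suspicion", "principal concern",
  "foremost possibility", "ranked first", "primary candidate",
  "prioritized diagnosis")

DATA_LEXICON <- c(
  "elevated troponin", "bilateral crackles", "productive cough",
  "pleuritic discomfort", "leukocytosis", "bandemia", "lactic acidemia",
  "hypoxemia", "tachypnea", "jugular venous distention", "pedal edema",
  "orthopnea", "rigors", "dysuria", "flank tenderness", "pyuria",
  "rebound tenderness", "guarding", "lipase elevation", "transaminitis",
  "hyperbilirubinemia", "asterixis", "nuchal rigidity", "photophobia",
  "focal weakness", "dysarthria", "anisocoria", "hyperglycemia",
  "anion gap", "ketonuria", "azotemia", "oliguria", "myoglobinuria",
  "thrombocytopenia", "schistocytes", "coagulopathy", "holosystolic murmur",
  "friction rub", "wheezing", "tripod posture")

LINK_LEXICON <- c(
  "consistent with", "suggestive of", "supported by", "attributable to",
  "implicating", "corroborating", "pointing toward", "evidencing",
  "substantiating", "arguing for", "reflecting", "signaling",
  "heralding", "denoting", "underpinning")

DISTRACTOR_VOCABULARY <- c(
  "admitted overnight", "remains comfortable", "tolerating oral intake",
  "ambulating without assistance", "family updated at bedside",
  "home medications reconciled", "code preferences confirmed",
  "nursing checks ongoing", "social work consulted",
  "physical therapy following", "sleep adequate", "appetite preserved",
  "vitals reviewed this morning", "telemetry uneventful",
  "daily labs pending")

# Synonym table for runtime text augmentation: common clinical words and
# their informal or expanded variants.
AUGMENT_SYNONYMS <- c(
  patient = "pt", history = "hx", treatment = "tx", diagnosis = "dx",
  symptoms = "sx", fracture = "fx", prescription = "rx", bilateral = "b/l",
  without = "w/o", hours = "hrs", morning = "am", evening = "pm",
  blood = "serum", exam = "examination", improved = "better",
  worsening = "deteriorating", severe = "marked", mild = "slight",
  chronic = "longstanding", acute = "new-onset", normal = "unremarkable",
  elevated = "raised", decreased = "reduced", reports = "endorses",
  denies = "refutes", continue = "maintain", monitor = "observe",
  start = "initiate", stop = "discontinue", follow = "track")

#' Packaged entity lexicons
#'
#' Phrase lists used by the synthetic-note generator, the dictionary
#' tagger baseline and the augmentation synonym sampler. The five entity
#' lexicons are pairwise disjoint and no phrase contains sentence
#' punctuation.
#'
#' @return A named list with elements `Dx`, `DC`, `Prior`, `Data`,
#'   `Link`, `distractor` and `synonyms`.
#' @export
default_lexicons <- function() {
  list(Dx = DX_LEXICON, DC = DC_LEXICON, Prior = PRIOR_LEXICON,
       Data = DATA_LEXICON, Link = LINK_LEXICON,
       distractor = DISTRACTOR_VOCABULARY, synonyms = AUGMENT_SYNONYMS)
}
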