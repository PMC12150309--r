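# Shared controlled vocabularies (defined first in collation order).

# Differential-effect classes a simulated feature can carry.
FEATURE_CLASSES <- c("null", "shared_inflammation", "progressive",
                     "sepsis_specific", "sins_specific", "sex_specific",
                     "pathogen_specific")

# Continuous confounders eligible for planted loadings, in fixed order.
CONTINUOUS_CONFOUNDERS <- c("gestational_age", "birthweight", "postnatal_age",
                            "tpn_proportion", "oxygen_pct")

# The ten clinical confounders with their types.
DEFAULT_COVARIATES <- c(gestational_age = "continuous", birthweight = "continuous",
                        postnatal_age = "continuous", tpn_proportion = "continuous",
                        oxygen_pct = "continuous", sex = "categorical",
                        sample_source = "categorical",
                        mechanical_ventilation = "categorical",
                        ivh = "categorical", antibiotics_24h = "categorical")

TREND_CATEGORIES <- c("shared_inflammation", "progressive_up", "progressive_down",
                      "sepsis_specific", "sins_specific", "unclassified")

METADATA_REQUIRED <- c("sample_id", "subject_id", "group", "is_followup",
                       "episode_index", "sex", "pathogen_type",
                       names(DEFAULT_COVARIATES), "IL6", "CRP", "PCT")
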