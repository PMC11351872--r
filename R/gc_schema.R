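# Built-in gastric-cancer cohort schema: 37 baseline variables collected at
# surgery (demographics, labs, tumor markers, histopathology, IHC/molecular
# status) for a 1000-patient cohort. The per-state counts and the continuous
# medians/ranges are kept alongside the state labels because the synthetic
# cohort generator calibrates its marginals to them.

# continuous variables: printed median and observed range
.gc_continuous <- data.frame(
  name = c("age", "BMI", "lymphocyte_count", "leukocyte_count", "AFP",
           "CA724", "CA125", "CA153", "CEA", "Ki67_expression",
           "Topo_expression", "max_diameter"),
  median = c(64, 23.1, 1.41, 6.4, 2.46, 2.2, 10.7, 7, 2.3, 0.6, 0.4, 3),
  min    = c(24, 14.2, 0.12, 2.66, 0.74, 0.37, 2.7, 2.7, 0.5, 0.01, 0.01, 0.8),
  max    = c(93, 54.1, 3.81, 27.58, 136.41, 300, 391.4, 20.2, 1500, 0.9,
             0.9, 18),
  units  = c("years", "kg/m2", "10^9/L", "10^9/L", "ng/mL", "U/mL", "U/mL",
             "U/mL", "ng/mL", "fraction", "fraction", "cm"),
  stringsAsFactors = FALSE)

# binary/categorical variables: state labels with per-state head counts out
# of 1000; an "NA" entry is the count of patients with the value unrecorded
.gc_categorical <- list(
  operater_codeEMR = list(kind = "categorical", counts = c(
    Laparotomy = 585, Laparoscope = 283,
    Laparoscopic_exploratory_surgery = 120, "NA" = 12)),
  Complications = list(kind = "binary", counts = c(Yes = 288, No = 712)),
  Tumor_location = list(kind = "categorical", counts = c(
    Lower = 408, Middle = 222, Upper = 360, Residual = 10)),
  pT = list(kind = "categorical", counts = c(
    "Tis/T1" = 309, T2 = 112, T3 = 394, T4a = 172, T4b = 13)),
  pN = list(kind = "categorical", counts = c(
    N0 = 447, N1 = 162, N2 = 157, N3a = 149, N3b = 85)),
  M = list(kind = "categorical", counts = c(
    M0 = 299, M1 = 6, Mx = 134, "NA" = 561)),
  AJCC_Stage = list(kind = "categorical", counts = c(
    "Stage 0/stage I" = 338, "Stage II" = 278, "Stage III" = 378,
    "Stage IV" = 6)),
  Sample_type = list(kind = "categorical", counts = c(
    Proximal = 68, Total = 409, Distal = 508, Residual = 15)),
  Differentiation = list(kind = "categorical", counts = c(
    High = 26, Middle = 367, Poorly = 365, Middle_poorly = 233,
    High_middle = 9)),
  Lauren = list(kind = "categorical", counts = c(
    "Intestinal type" = 128, "Diffuse type" = 124, Mixed = 76, "NA" = 672)),
  Nerve_invasion = list(kind = "binary", counts = c(Yes = 433, No = 567)),
  Tumor_thrombus = list(kind = "binary", counts = c(Yes = 353, No = 647)),
  Cancerous_node = list(kind = "binary", counts = c(Yes = 138, No = 862)),
  Positive_margin = list(kind = "binary", counts = c(Yes = 138, No = 862)),
  Surgical_complications = list(kind = "binary", counts = c(Yes = 31,
                                                            No = 969)),
  Omental_involvement = list(kind = "binary", counts = c(
    Yes = 7, No = 295, "NA" = 698)),
  TRG = list(kind = "categorical", counts = c(
    "1 grade" = 1, "2 grade" = 4, "3 grade" = 5, "NA" = 990)),
  MLH1_IHC = list(kind = "categorical", counts = c(
    "(-)" = 20, "(+)" = 363, "NA" = 617)),
  MSH2_IHC = list(kind = "categorical", counts = c(
    "(-)" = 13, "(+)" = 357, "Little (+)" = 12, "NA" = 618)),
  MSH6_IHC = list(kind = "categorical", counts = c(
    "(-)" = 6, "(+)" = 320, "Little (+)" = 48, "NA" = 626)),
  PMS2_IHC = list(kind = "categorical", counts = c(
    "(-)" = 19, "(+)" = 363, "NA" = 618)),
  dMMR = list(kind = "binary", counts = c(Yes = 38, No = 332, "NA" = 630)),
  `EGFR-IHC` = list(kind = "categorical", counts = stats::setNames(
    c(586, 406, 8), c("(-)", "(+)", "(\u00b1)"))),
  `ERBB2-IHC` = list(kind = "categorical", counts = c(
    "(-)" = 663, "(+)" = 337)),
  `p53-IHC` = list(kind = "categorical", counts = c(
    "(-)" = 183, "(+)" = 185, "NA" = 632))
)

# internal accessor used by the generator and the summary reconstruction check
gc_marginals <- function() {
  list(continuous = .gc_continuous,
       categorical = .gc_categorical,
       n = 1000L)
}

#' Built-in gastric-cancer baseline schema
#'
#' The variable schema of a 1000-patient surgical gastric-cancer cohort:
#' 12 continuous variables (demographics, blood counts, serum tumor
#' markers, expression fractions, tumor size) and 25 binary/categorical
#' variables (surgical approach, histopathology, TNM/AJCC staging, Lauren
#' type, mismatch-repair and IHC marker status). Variables that were not
#' recorded for part of the cohort carry the explicit `"NA"` state; all
#' continuous variables allow missingness. Under quartile encoding this
#' schema yields 143 one-hot features.
#'
#' @return A `cpsn_schema` with 37 variables.
#' @examples
#' s <- gc_schema()
#' length(s)    # 37
#' n_states(s)  # 143
#' @export
gc_schema <- function() {
  cont <- lapply(seq_len(nrow(.gc_continuous)), function(i)
    variable_spec(.gc_continuous$name[i], "continuous",
                  allow_missing = TRUE, units = .gc_continuous$units[i]))
  cat_ <- lapply(names(.gc_categorical), function(nm) {
    v <- .gc_categorical[[nm]]
    st <- names(v$counts)
    variable_spec(nm, v$kind, states = st,
                  allow_missing = "NA" %in% st)
  })
  cohort_schema(c(cont, cat_), name = "gastric_cancer_baseline",
                version = "1")
}
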