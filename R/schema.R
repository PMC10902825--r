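# Shared vocabulary: level sets, canonical column names, alias profiles.

# Five-step severity lattice used for valve lesions; "none" doubles as
# "not stated" for lesions that clinicians omit when absent.
severity_levels <- function() {
  c("none", "mild", "mild-to-moderate", "moderate", "moderate-to-severe",
    "severe")
}

stenosis_av_levels <- function() {
  c("none", "sclerosis", "mild", "mild-to-moderate", "moderate",
    "moderate-to-severe", "severe", "AVR")
}

function_levels <- function() {
  c("normal", "mildly impaired", "mild-to-moderately impaired",
    "moderately impaired", "moderate-to-severely impaired",
    "severely impaired", "not stated")
}

size_levels <- function() {
  c("normal", "mild", "moderate", "severe", "not stated")
}

rhythm_levels <- function() {
  c("artificially paced", "supraventricular tachycardia", "atrial flutter",
    "atrial fibrillation", "heart block", "sinus rhythm", "other",
    "uncertain")
}

bbb_levels <- function() {
  c("left BBB", "right BBB", "BBB (unspecified)", "no BBB")
}

morphology_levels <- function() c("tricuspid", "bicuspid", "exclude")

binary_levels <- function() c("none", "present")

diastolic_levels <- function() {
  c("normal", "dysfunction", "grade I", "grade II", "grade III",
    "indeterminate", "not assessable")
}

# Canonical (post-aliasing) column names of a raw study row.
raw_schema <- function() {
  c("nhi", "study_date", "age", "sex", "height", "weight", "heart_rate",
    "rhythm_text", "indication_text", "lv_text", "la_text", "rv_text",
    "mitral_text", "aov_text", "pulmonary_text", "tricuspid_text",
    "rvsp_text", "rvsp", "ivsd", "lvpwd", "lvot_diam",
    "lvef_biplane", "lvef_a4c", "lvef_a2c", "lvef_teichholz",
    "lvef_mmode_cube", "lvef_mmode",
    "mitral_e", "mitral_a", "e_over_a", "e_over_e_prime",
    "septal_e_prime", "lateral_e_prime",
    "asc_aorta", "aortic_root", "aov_vmax", "aov_mean_grad", "aov_vti",
    "aov_area", "lvot_vti", "tr_vmax", "lavi", "comments")
}

# Free-text source columns; dropped from the export.
text_columns <- function() {
  c("rhythm_text", "indication_text", "lv_text", "la_text", "rv_text",
    "mitral_text", "aov_text", "pulmonary_text", "tricuspid_text",
    "rvsp_text", "comments")
}

# Categorical variables recovered from free text (Table 3 shape), mapped to
# the free-text section each is read from.
categorical_schema <- function() {
  tibble::tibble(
    variable = c("aortic_stenosis", "aortic_regurgitation", "av_morphology",
                 "mitral_stenosis", "mac", "mitral_regurgitation",
                 "mitral_prolapse", "tricuspid_regurgitation",
                 "pulmonary_stenosis", "pulmonary_regurgitation",
                 "lv_size", "lv_function", "la_size", "rv_size",
                 "rv_function", "rhythm", "bbb"),
    section = c("aov_text", "aov_text", "aov_text",
                "mitral_text", "mitral_text", "mitral_text", "mitral_text",
                "tricuspid_text", "pulmonary_text", "pulmonary_text",
                "lv_text", "lv_text", "la_text", "rv_text", "rv_text",
                "rhythm_text", "rhythm_text")
  )
}

#' Column-name alias profiles for heterogeneous report versions
#'
#' PACS data-mining exports name the same variable differently across
#' report versions. An alias profile records, for one report version, the
#' display header used for each canonical variable plus the date format of
#' its study-date column. [stitch_chunks()] uses these profiles to unify
#' chunks into a single table with canonical names.
#'
#' @return A named list of profiles. Each profile is a list with elements
#'   `name`, `date_format` (a [strptime()] format), and `columns`, a named
#'   character vector mapping canonical name -> display header.
#' @export
#' @examples
#' names(default_alias_profiles())
#' default_alias_profiles()$v2$columns[["heart_rate"]]
default_alias_profiles <- function() {
  canon <- raw_schema()
  v1 <- c(
    nhi = "NHI", study_date = "StudyDate", age = "Age", sex = "Sex",
    height = "Height", weight = "Weight", heart_rate = "HeartRate",
    rhythm_text = "RhythmText", indication_text = "IndicationText",
    lv_text = "LVText", la_text = "LAText", rv_text = "RVText",
    mitral_text = "MitralText", aov_text = "AoVText",
    pulmonary_text = "PulmText", tricuspid_text = "TricuspidText",
    rvsp_text = "RVSPText", rvsp = "RVSP", ivsd = "IVSd", lvpwd = "LVPWd",
    lvot_diam = "LVOTDiam", lvef_biplane = "LVEF_Biplane",
    lvef_a4c = "LVEF_A4C", lvef_a2c = "LVEF_A2C",
    lvef_teichholz = "LVEF_Teichholz", lvef_mmode_cube = "LVEF_MModeCube",
    lvef_mmode = "LVEF_MMode", mitral_e = "MitralE", mitral_a = "MitralA",
    e_over_a = "EoverA", e_over_e_prime = "EoverEprime",
    septal_e_prime = "SeptalEprime", lateral_e_prime = "LateralEprime",
    asc_aorta = "AscAorta", aortic_root = "AorticRoot", aov_vmax = "AoVVmax",
    aov_mean_grad = "AoVMeanGrad", aov_vti = "AoVVTI", aov_area = "AoVArea",
    lvot_vti = "LVOTVTI", tr_vmax = "TRVmax", lavi = "LAVi",
    comments = "Comments"
  )
  v2 <- c(
    nhi = "Patient NHI", study_date = "Date of Study", age = "Patient Age",
    sex = "Patient Sex", height = "Height (m)", weight = "Weight (kg)",
    heart_rate = "HR (bpm)", rhythm_text = "Rhythm",
    indication_text = "Indication", lv_text = "Left Ventricle",
    la_text = "Left Atrium", rv_text = "Right Ventricle",
    mitral_text = "Mitral Valve", aov_text = "Aortic Valve",
    pulmonary_text = "Pulmonary Valve", tricuspid_text = "Tricuspid Valve",
    rvsp_text = "RVSP Comment", rvsp = "RVSP (mmHg)", ivsd = "IVSd (cm)",
    lvpwd = "LVPWd (cm)", lvot_diam = "LVOT Diameter",
    lvef_biplane = "LVEF Modified Biplane", lvef_a4c = "LVEF Modified A4C",
    lvef_a2c = "LVEF Modified A2C", lvef_teichholz = "LVEF Teichholz 2D",
    lvef_mmode_cube = "LVEF M-Mode Cube", lvef_mmode = "LVEF M-Mode",
    mitral_e = "Mitral E (cm/s)", mitral_a = "Mitral A (cm/s)",
    e_over_a = "Mitral E/A", e_over_e_prime = "Mitral E/e'",
    septal_e_prime = "Septal e'", lateral_e_prime = "Lateral e'",
    asc_aorta = "Ascending Aorta", aortic_root = "Aortic Root",
    aov_vmax = "AoV Vmax (m/s)", aov_mean_grad = "AoV Mean Gradient",
    aov_vti = "AoV VTI", aov_area = "AoV Area (cm2)", lvot_vti = "LVOT VTI",
    tr_vmax = "TR Vmax (m/s)", lavi = "LAVi (mL/m2)", comments = "Comments"
  )
  stopifnot(setequal(names(v1), canon), setequal(names(v2), canon))
  list(
    v1 = list(name = "v1", date_format = "%Y-%m-%d", columns = v1[canon]),
    v2 = list(name = "v2", date_format = "%d/%m/%Y", columns = v2[canon])
  )
}
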