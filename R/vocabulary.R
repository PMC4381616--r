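#' Controlled vocabularies for primary and secondary sites
#'
#' The registry data model uses two fixed vocabularies: 16 primary-site
#' categories and 20 secondary-site codes. Secondary sites are anatomical
#' locations harboring metastasis; \code{OTH} collects rarer locations.
#' Regional lymph-node involvement is *not* a secondary site (it is carried
#' by \code{nodal_status}); only non-regional nodes (\code{LYM}) count as
#' metastasis.
#'
#' @return \code{primary_sites()} returns the 16 primary-site labels;
#'   \code{secondary_sites()} the 20 secondary-site codes;
#'   \code{smoking_related_sites()} the 7 primary sites classified as
#'   smoking-related (population attributable fraction of smoking >= 20%).
#' @examples
#' length(primary_sites())     # 16
#' length(secondary_sites())   # 20
#' @export
primary_sites <- function() {
  c("lung", "esophagus and stomach", "colon and rectum", "breast",
    "pancreas", "biliary system", "head and neck", "kidney",
    "neuroendocrine tumors", "prostate", "liver", "urinary tract",
    "melanoma", "ovary", "cervix", "testicles")
}

#' @rdname primary_sites
#' @export
secondary_sites <- function() {
  c("ADR", "OSS", "MAR", "BRA", "HEA", "REN", "HEP", "PUL", "LYM", "MEN",
    "OVA", "PAN", "PC", "PER", "PLE", "SKI", "ST", "SPL", "THY", "OTH")
}

#' @rdname primary_sites
#' @export
smoking_related_sites <- function() {
  c("lung", "head and neck", "esophagus and stomach", "kidney",
    "pancreas", "urinary tract", "cervix")
}

#' Long-form names of the secondary-site codes (for reporting only).
#' @noRd
secondary_site_names <- function() {
  c(ADR = "adrenal gland", OSS = "bone", MAR = "bone marrow", BRA = "brain",
    HEA = "heart", REN = "kidney", HEP = "liver", PUL = "lung",
    LYM = "non-regional lymph nodes", MEN = "meninges", OVA = "ovary",
    PAN = "pancreas", PC = "pericardium", PER = "peritoneum", PLE = "pleura",
    SKI = "skin", ST = "soft tissue", SPL = "spleen", THY = "thyroid",
    OTH = "other site")
}

#' Sentinel label used for metastatic cases whose primary is a rare tumor
#' (or that have multiple primaries) and therefore fall outside the 16
#' categories.
#' @export
rare_primary_sentinel <- function() "rare/other"

met_cols <- function() paste0("met_", secondary_sites())

#' Classify a primary site as smoking-related or not
#'
#' Deterministic lookup against the fixed vocabulary: tumor types with a
#' smoking population attributable fraction >= 20% (lung, head and neck,
#' esophagus and stomach, kidney, pancreas, urinary tract, cervix) are
#' smoking-related; the remaining 9 sites are not.
#'
#' @param primary_site character vector of primary-site labels.
#' @return character vector, each element \code{"smoking_related"} or
#'   \code{"non_smoking_related"}.
#' @examples
#' classify_smoking("lung")      # smoking_related
#' classify_smoking("melanoma")  # non_smoking_related
#' @export
classify_smoking <- function(primary_site) {
  bad <- setdiff(primary_site, primary_sites())
  if (length(bad) > 0L) {
    stop("unknown primary site label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(primary_site %in% smoking_related_sites(),
         "smoking_related", "non_smoking_related")
}
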