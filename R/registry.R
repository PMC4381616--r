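#' Registry data model and file I/O
#'
#' A registry is a data frame with one row per autopsied patient and the
#' canonical columns \code{id, age_at_death, sex, autopsy_year, has_cancer,
#' n_primaries, primary_site, histology, nodal_status, met_ADR ... met_OTH,
#' cancer_related_death}. The 20 \code{met_*} columns are 0/1 indicators
#' aligned with \code{\link{secondary_sites}}.
#' @name registry
NULL

REQUIRED_COLS <- c("id", "age_at_death", "sex", "autopsy_year", "has_cancer",
                   "n_primaries", "primary_site", "cancer_related_death")

new_registry <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("met_registry", "data.frame")
  df
}

#' Extract the n x 20 metastasis indicator matrix from a registry or cohort
#'
#' @param x a registry data frame or a \code{met_cohort}.
#' @return integer matrix with one row per patient and the 20 secondary-site
#'   codes as column names.
#' @export
met_matrix <- function(x) {
  if (inherits(x, "met_cohort")) x <- x$included
  m <- as.matrix(x[, met_cols(), drop = FALSE])
  storage.mode(m) <- "integer"
  colnames(m) <- secondary_sites()
  m
}

parse_logical <- function(x, col, rows) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) {
    stop("unparseable ", col, " in row(s) ",
         paste(rows[which(is.na(out))[1]], collapse = ", "))
  }
  out
}

parse_numeric <- function(x, col, rows) {
  out <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(is.na(out) & !(is.na(x) | trimws(as.character(x)) == ""))
  bad <- c(bad, which(is.na(x) | trimws(as.character(x)) == ""))
  if (length(bad) > 0L) {
    stop("unparseable ", col, " in row ", rows[min(bad)])
  }
  out
}

mets_from_list <- function(codes) {
  m <- matrix(0L, nrow = length(codes), ncol = 20L,
              dimnames = list(NULL, met_cols()))
  unknown <- character(0)
  for (i in seq_along(codes)) {
    s <- trimws(strsplit(as.character(codes[i]), ";", fixed = TRUE)[[1]])
    s <- s[nzchar(s)]
    if (length(s) == 0L) next
    bad <- !(s %in% secondary_sites())
    if (any(bad)) {
      unknown <- c(unknown, s[bad])
      s[bad] <- "OTH"
    }
    m[i, paste0("met_", unique(s))] <- 1L
  }
  if (length(unknown) > 0L) {
    warning("unrecognized secondary-site code(s) mapped to OTH: ",
            paste(unique(unknown), collapse = ", "))
  }
  m
}

#' Read a patient registry from a delimited file
#'
#' Accepts UTF-8 CSV or TSV with a header row. Metastasis sites may be given
#' either as a single \code{mets} column holding a semicolon-joined code list
#' (e.g. \code{"HEP;PUL;OSS"}) or as 20 indicator columns
#' \code{met_ADR ... met_OTH}. Unrecognized secondary codes are mapped to
#' \code{OTH} with a warning; missing \code{histology}/\code{nodal_status}
#' become \code{"unknown"}.
#'
#' @param path file to read.
#' @param delim field delimiter; \code{NULL} (default) infers \code{"\t"}
#'   for \code{.tsv}/\code{.tab} files and \code{","} otherwise.
#' @return a registry data frame (class \code{met_registry}).
#' @seealso [write_registry()], [apply_inclusion_filters()]
#' @export
read_registry <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  has_list <- "mets" %in% names(raw)
  has_wide <- all(met_cols() %in% names(raw))
  if (!has_list && !has_wide) {
    stop("missing required column(s): mets (or the 20 met_* indicator columns)")
  }
  n <- nrow(raw)
  if (n == 0L) {
    df <- empty_registry()
    return(df)
  }
  rows <- seq_len(n)
  sex <- tolower(trimws(raw$sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("invalid sex value in row ",
         rows[which(!sex %in% c("male", "female"))[1]],
         " (expected male/female)")
  }
  histology <- if ("histology" %in% names(raw)) {
    h <- tolower(trimws(raw$histology))
    h[!nzchar(h) | is.na(h)] <- "unknown"
    ok <- h %in% c("adenocarcinoma", "squamous", "other", "unknown")
    h[!ok] <- "other"
    h
  } else rep("unknown", n)
  nodal <- if ("nodal_status" %in% names(raw)) {
    v <- trimws(raw$nodal_status)
    v[!nzchar(v) | is.na(v)] <- "unknown"
    ok <- v %in% c("N+", "N-", "unknown")
    v[!ok] <- "unknown"
    v
  } else rep("unknown", n)
  has_cancer <- parse_logical(raw$has_cancer, "has_cancer", rows)
  primary <- trimws(raw$primary_site)
  primary[!has_cancer] <- NA_character_
  with_cancer <- which(has_cancer)
  odd <- with_cancer[!(primary[with_cancer] %in%
                         c(primary_sites(), rare_primary_sentinel()))]
  if (length(odd) > 0L) {
    warning(length(odd), " record(s) with unrecognized primary_site mapped to '",
            rare_primary_sentinel(), "'")
    primary[odd] <- rare_primary_sentinel()
  }
  mets <- if (has_wide) {
    m <- vapply(met_cols(), function(cc) {
      as.integer(parse_numeric(raw[[cc]], cc, rows))
    }, integer(n))
    if (n == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, met_cols()))
    m
  } else {
    mets_from_list(raw$mets)
  }
  df <- data.frame(
    id = as.character(raw$id),
    age_at_death = parse_numeric(raw$age_at_death, "age_at_death", rows),
    sex = sex,
    autopsy_year = as.integer(parse_numeric(raw$autopsy_year, "autopsy_year",
                                            rows)),
    has_cancer = has_cancer,
    n_primaries = as.integer(parse_numeric(raw$n_primaries, "n_primaries",
                                           rows)),
    primary_site = primary,
    histology = histology,
    nodal_status = nodal,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(mets))
  df$cancer_related_death <- parse_logical(raw$cancer_related_death,
                                           "cancer_related_death", rows)
  # type invariant: cancer-free records carry no primaries and no metastases
  bad <- which(!df$has_cancer & (df$n_primaries != 0L |
                                   rowSums(mets) > 0L))
  if (length(bad) > 0L) {
    stop("row ", bad[1],
         ": has_cancer is false but n_primaries > 0 or metastases recorded")
  }
  new_registry(df)
}

empty_registry <- function() {
  df <- data.frame(
    id = character(0), age_at_death = numeric(0), sex = character(0),
    autopsy_year = integer(0), has_cancer = logical(0),
    n_primaries = integer(0), primary_site = character(0),
    histology = character(0), nodal_status = character(0),
    stringsAsFactors = FALSE
  )
  for (cc in met_cols()) df[[cc]] <- integer(0)
  df$cancer_related_death <- logical(0)
  new_registry(df)
}

#' Write a registry to a delimited file
#'
#' @param registry a registry data frame.
#' @param path output file.
#' @param delim field delimiter (default comma).
#' @param mets_as \code{"columns"} (default) writes the 20 \code{met_*}
#'   indicator columns; \code{"list"} writes one semicolon-joined
#'   \code{mets} column.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path, delim = ",",
                           mets_as = c("columns", "list")) {
  mets_as <- match.arg(mets_as)
  df <- as.data.frame(registry)
  if (mets_as == "list") {
    m <- met_matrix(registry)
    df$mets <- apply(m, 1L, function(r) {
      paste(secondary_sites()[r == 1L], collapse = ";")
    })
    df <- df[, c(setdiff(names(df), c(met_cols(), "mets",
                                      "cancer_related_death")),
                 "mets", "cancer_related_death")]
  }
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Apply the inclusion-filter cascade to a registry
#'
#' Filters a raw registry down to the analysis cohort in a fixed order:
#' (1) drop patients without cancer; (2) drop cancer patients without any
#' metastasis; (3) drop metastatic patients with rare primaries or more than
#' one primary. Each excluded record is counted once, under the first
#' matching reason, so the audit trail is deterministic.
#'
#' @param registry a registry data frame (see [read_registry()]).
#' @return a \code{met_cohort}: list with \code{included} (registry of
#'   eligible patients), \code{exclusions} (named counts by reason) and
#'   \code{n_total}.
#' @examples
#' reg <- generate_registry(synthetic_config(n_total = 500, seed = 1))
#' coh <- apply_inclusion_filters(reg)
#' coh$exclusions
#' @export
apply_inclusion_filters <- function(registry) {
  df <- as.data.frame(registry)
  n_total <- nrow(df)
  m <- if (n_total > 0L) rowSums(df[, met_cols(), drop = FALSE]) else integer(0)
  no_cancer <- !df$has_cancer
  no_mets <- !no_cancer & m == 0L
  rare_mult <- !no_cancer & !no_mets &
    (df$n_primaries != 1L | is.na(df$primary_site) |
       !(df$primary_site %in% primary_sites()))
  keep <- !(no_cancer | no_mets | rare_mult)
  cohort <- list(
    included = new_registry(df[keep, , drop = FALSE]),
    exclusions = c(no_cancer = sum(no_cancer),
                   no_metastasis = sum(no_mets),
                   rare_or_multiple_primary = sum(rare_mult)),
    n_total = n_total
  )
  class(cohort) <- "met_cohort"
  cohort
}

#' @export
print.met_cohort <- function(x, ...) {
  cat("Metastatic-cancer cohort\n")
  cat("  autopsied records:", x$n_total, "\n")
  cat("  included:         ", nrow(x$included), "\n")
  cat("  excluded: no cancer", x$exclusions[["no_cancer"]],
      "| no metastasis", x$exclusions[["no_metastasis"]],
      "| rare/multiple primary", x$exclusions[["rare_or_multiple_primary"]],
      "\n")
  if (nrow(x$included) > 0L) {
    tab <- sort(table(x$included$primary_site), decreasing = TRUE)
    cat("  primaries:", paste0(names(tab)[seq_len(min(4, length(tab)))], " (",
                               tab[seq_len(min(4, length(tab)))], ")",
                               collapse = ", "),
        if (length(tab) > 4L) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.met_cohort <- function(object, ...) {
  list(
    n_total = object$n_total,
    n_included = nrow(object$included),
    exclusions = object$exclusions,
    primaries = table(object$included$primary_site),
    site_hits = colSums(met_matrix(object))
  )
}

cohort_size <- function(cohort) nrow(cohort$included)
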