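ICD10_SHAPE <- "^[A-Z][0-9]{2}[0-9A-Z]?$"

#' Normalize ICD-10 codes
#'
#' Uppercases and strips the optional dot, so `"j06.9"` and `"J069"` are the
#' same code.  ICD-10 dialects differ on dot usage; all package internals
#' work on the dot-free form.
#'
#' @param code Character vector of raw ICD-10 codes.
#' @return Character vector of normalized codes.
#' @export
normalize_icd10 <- function(code) {
  toupper(gsub(".", "", as.character(code), fixed = TRUE))
}

#' Path to the shipped default category catalog
#'
#' @return File path of the default catalog installed with the package.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "default_catalog.yaml", package = "episodizer",
              mustWork = TRUE)
}

#' Load an infection-category catalog
#'
#' The catalog maps ICD-10 code prefixes to numbered infection categories,
#' each carrying one of five code classes: `RESPIRATORY`,
#' `GASTROINTESTINAL` (infective gastroenteritis), `GI_SYMPTOM`
#' (gastroenteritis symptom codes, reserved for category "8"),
#' `FEVER_MARKER` (the fever symptom code, reserved for category "1") and
#' `OTHER`.  The shipped default is a documented ICD-10 reconstruction of
#' the published category names (the authoritative code lists were never
#' published) and is intended to be overridden by a user file of the same
#' schema.
#'
#' A Fahrenheit fever threshold (`fever_threshold_f`) is converted to
#' Celsius at load time, so the catalog always carries a single Celsius
#' threshold (default 38.0; 101 F loads as 38.33 C).
#'
#' @param path Path to a YAML catalog file, or `NULL` for the shipped
#'   default.
#' @return An object of class `infection_catalog`: a list with `version`,
#'   `fever_threshold_c`, `categories` (data.frame: `category_id`, `name`,
#'   `episode_class`, `site_tag`) and `patterns` (data.frame: `pattern`,
#'   `category_id`, `episode_class`).
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) path <- default_catalog_path()
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_input("catalog file does not parse as YAML: ", conditionMessage(e),
               class = "catalog_schema_error")
  })
  if (!is.list(raw) || is.null(raw$categories) || !length(raw$categories)) {
    stop_input("catalog file defines no categories",
               class = "catalog_schema_error")
  }
  thr <- raw$fever_threshold_c
  if (is.null(thr) && !is.null(raw$fever_threshold_f)) {
    thr <- round((raw$fever_threshold_f - 32) * 5 / 9, 2)
  }
  thr <- thr %||% 38.0
  cats <- lapply(seq_along(raw$categories), function(i) {
    entry <- raw$categories[[i]]
    for (field in c("id", "name", "class", "patterns")) {
      if (is.null(entry[[field]])) {
        stop_input("catalog entry ", i, " (id: ",
                   entry$id %||% "<missing>", ") lacks field '", field, "'",
                   class = "catalog_schema_error")
      }
    }
    if (!entry$class %in% CODE_CLASSES) {
      stop_input("catalog entry '", entry$id, "' has unknown class '",
                 entry$class, "' (allowed: ",
                 paste(CODE_CLASSES, collapse = ", "), ")",
                 class = "catalog_schema_error")
    }
    list(category_id = as.character(entry$id), name = entry$name,
         episode_class = entry$class,
         site_tag = entry$site_tag %||% NA_character_,
         patterns = normalize_icd10(unlist(entry$patterns)))
  })
  categories <- data.frame(
    category_id = vapply(cats, `[[`, "", "category_id"),
    name = vapply(cats, `[[`, "", "name"),
    episode_class = vapply(cats, `[[`, "", "episode_class"),
    site_tag = vapply(cats, `[[`, "", "site_tag"),
    stringsAsFactors = FALSE)
  patterns <- data.frame(
    pattern = unlist(lapply(cats, `[[`, "patterns")),
    category_id = rep(categories$category_id,
                      vapply(cats, function(x) length(x$patterns), 0L)),
    stringsAsFactors = FALSE)
  patterns$episode_class <-
    categories$episode_class[match(patterns$category_id,
                                   categories$category_id)]
  catalog <- structure(
    list(version = as.character(raw$version %||% "unversioned"),
         fever_threshold_c = as.numeric(thr),
         categories = categories, patterns = patterns),
    class = "infection_catalog")
  issues <- validate_catalog(catalog)
  if (length(issues)) {
    dup <- grepl("^duplicate pattern", issues)
    stop_input(paste(issues, collapse = "; "),
               class = if (any(dup)) "catalog_conflict_error"
                       else "catalog_schema_error")
  }
  catalog
}

#' Save a catalog to a YAML file
#'
#' @param catalog An `infection_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "infection_catalog"))
  cats <- lapply(seq_len(nrow(catalog$categories)), function(i) {
    row <- catalog$categories[i, ]
    pats <- catalog$patterns$pattern[
      catalog$patterns$category_id == row$category_id]
    entry <- list(id = row$category_id, name = row$name,
                  class = row$episode_class, patterns = as.list(pats))
    if (!is.na(row$site_tag)) entry$site_tag <- row$site_tag
    entry
  })
  yaml::write_yaml(list(version = catalog$version,
                        fever_threshold_c = catalog$fever_threshold_c,
                        categories = cats), path)
  invisible(path)
}

#' Validate a catalog against its structural rules
#'
#' Checks: category ids unique; every pattern has the ICD-10 shape (letter,
#' two digits, optional fourth alphanumeric); no pattern mapped to two
#' categories; `GI_SYMPTOM` used only by category "8" and `FEVER_MARKER`
#' only by category "1"; the three coded episode classes all represented.
#' Validation never raises; it returns the list of problems.
#'
#' @param catalog An `infection_catalog`.
#' @return Character vector of issues; empty when the catalog is valid.
#' @export
validate_catalog <- function(catalog) {
  issues <- character(0)
  cats <- catalog$categories
  pats <- catalog$patterns
  dup_id <- unique(cats$category_id[duplicated(cats$category_id)])
  for (d in dup_id) {
    issues <- c(issues, paste0("category '", d, "': duplicate category_id"))
  }
  bad <- pats$pattern[!grepl(ICD10_SHAPE, pats$pattern)]
  for (b in unique(bad)) {
    issues <- c(issues,
                paste0("category '",
                       paste(pats$category_id[pats$pattern == b],
                             collapse = ","),
                       "': pattern '", b, "' is not ICD-10 shaped"))
  }
  dup_pat <- unique(pats$pattern[duplicated(pats$pattern)])
  for (p in dup_pat) {
    issues <- c(issues,
                paste0("duplicate pattern '", p, "' mapped by categories ",
                       paste(unique(pats$category_id[pats$pattern == p]),
                             collapse = " and ")))
  }
  off <- cats$category_id[cats$episode_class == "GI_SYMPTOM" &
                            cats$category_id != "8"]
  for (o in off) {
    issues <- c(issues, paste0("category '", o,
                               "': class GI_SYMPTOM is reserved for category 8"))
  }
  off <- cats$category_id[cats$episode_class == "FEVER_MARKER" &
                            cats$category_id != "1"]
  for (o in off) {
    issues <- c(issues, paste0("category '", o,
                               "': class FEVER_MARKER is reserved for category 1"))
  }
  for (cl in c("RESPIRATORY", "GASTROINTESTINAL", "OTHER")) {
    if (!cl %in% cats$episode_class) {
      issues <- c(issues, paste0("catalog: no category with class ", cl))
    }
  }
  if (!is.numeric(catalog$fever_threshold_c) ||
      length(catalog$fever_threshold_c) != 1 ||
      is.na(catalog$fever_threshold_c)) {
    issues <- c(issues, "catalog: fever_threshold_c must be a single number")
  }
  issues
}

#' Classify ICD-10 codes against a catalog
#'
#' Codes are normalized (uppercased, dot stripped) and matched against the
#' catalog's prefixes; the longest matching prefix wins, which is how nested
#' prefixes (e.g. a specific 4-character code inside a broader 3-character
#' family) are resolved.  Codes matching no pattern are returned as
#' `NOT_INFECTIOUS`.  The function is pure and vectorized.
#'
#' @param catalog An `infection_catalog`.
#' @param code Character vector of ICD-10 codes (dot allowed).
#' @return data.frame with `code` (normalized), `category_id` (NA when not
#'   infectious) and `episode_class` (`"NOT_INFECTIOUS"` when unmatched).
#' @export
classify_code <- function(catalog, code) {
  stopifnot(inherits(catalog, "infection_catalog"))
  norm <- normalize_icd10(code)
  bad <- norm[!grepl(ICD10_SHAPE, norm)]
  if (length(bad)) {
    stop_input("not ICD-10 shaped: ",
               paste(unique(bad), collapse = ", "),
               class = "icd10_format_error")
  }
  pats <- catalog$patterns
  # try the 4-character code itself, then its 3-character stem
  hit4 <- match(norm, pats$pattern)
  hit3 <- match(substr(norm, 1, 3), pats$pattern)
  hit <- ifelse(is.na(hit4), hit3, hit4)
  data.frame(
    code = norm,
    category_id = ifelse(is.na(hit), NA_character_, pats$category_id[hit]),
    episode_class = ifelse(is.na(hit), "NOT_INFECTIOUS",
                           pats$episode_class[hit]),
    stringsAsFactors = FALSE)
}

#' @export
print.infection_catalog <- function(x, ...) {
  cat("Infection-category catalog (version ", x$version, ")\n", sep = "")
  cat("  fever threshold: ", x$fever_threshold_c, " C\n", sep = "")
  tab <- table(x$categories$episode_class)
  cat("  ", nrow(x$categories), " categories, ", nrow(x$patterns),
      " code prefixes\n", sep = "")
  for (cl in names(tab)) {
    cat("    ", cl, ": ", tab[[cl]], " categories\n", sep = "")
  }
  invisible(x)
}
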