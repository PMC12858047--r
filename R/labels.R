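# ---------------------------------------------------------------------------
# Label harmonization: ICD-10 prefix maps, diagnostic-statement superclass
# merges, and per-patient deduplication.
# ---------------------------------------------------------------------------

#' Construct a label map
#'
#' An ordered rule set mapping ICD-10 code prefixes or diagnostic-statement
#' identifiers to target classes. Prefix rules match longest-first.
#'
#' @param rules data frame with columns `pattern` and `class`.
#' @param type `"prefix"` (ICD-10 codes) or `"statement"` (exact statement
#'   ids).
#' @return a `label_map`.
#' @export
label_map <- function(rules, type = c("prefix", "statement")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(rules), nrow(rules) >= 1,
            all(c("pattern", "class") %in% names(rules)))
  rules$pattern <- toupper(trimws(as.character(rules$pattern)))
  rules$class <- as.character(rules$class)
  rules <- rules[order(-nchar(rules$pattern)), , drop = FALSE]
  structure(list(rules = rules, type = type,
                 classes = sort(unique(rules$class))),
            class = "label_map")
}

#' Built-in label maps
#'
#' Ships the harmonization tables used throughout the package:
#' * `icd10_superclasses` - `I11`, `I51.7` -> HYP; `I21`, `I22` -> MI;
#'   `I44` -> CD.
#' * `icd10_infarcts` - `I21.0` -> AMI (anterior), `I21.1` -> IMI (inferior).
#' * `icd10_bbb` - `I44.7` -> LBBB, `I45.1` -> RBBB.
#' * `statement_superclasses` - conduction-disturbance statements (BBB,
#'   CLBBB, CRBBB, IRBBB, IAVB, LAnFB, NSIVCB) -> CD; T-wave/QT statements
#'   (TAb, TInv, LQT) -> STTC.
#' * `statement_bbb` - complete/incomplete variants merged into their
#'   superclass: CLBBB -> LBBB; CRBBB, IRBBB -> RBBB.
#'
#' @param name one of the map names above.
#' @return a `label_map`.
#' @export
builtin_label_map <- function(name = c("icd10_superclasses", "icd10_infarcts",
                                       "icd10_bbb", "statement_superclasses",
                                       "statement_bbb")) {
  name <- match.arg(name)
  tab <- switch(name,
    icd10_superclasses = data.frame(
      pattern = c("I11", "I51.7", "I21", "I22", "I44"),
      class = c("HYP", "HYP", "MI", "MI", "CD")),
    icd10_infarcts = data.frame(
      pattern = c("I21.0", "I21.1"),
      class = c("AMI", "IMI")),
    icd10_bbb = data.frame(
      pattern = c("I44.7", "I45.1"),
      class = c("LBBB", "RBBB")),
    statement_superclasses = data.frame(
      pattern = c("BBB", "CLBBB", "LBBB", "CRBBB", "RBBB", "IRBBB", "IAVB",
                  "LANFB", "NSIVCB", "TAB", "TINV", "LQT"),
      class = c(rep("CD", 9), rep("STTC", 3))),
    statement_bbb = data.frame(
      pattern = c("CLBBB", "CRBBB", "IRBBB", "LBBB", "RBBB"),
      class = c("LBBB", "RBBB", "RBBB", "LBBB", "RBBB")))
  label_map(tab, type = if (grepl("^icd10", name)) "prefix" else "statement")
}

#' Read or write a label map as CSV
#'
#' The on-disk form is a two-column CSV (`pattern`, `class`); rule order is
#' re-derived (longest prefix first) on read.
#'
#' @param map a `label_map`.
#' @param path CSV file path.
#' @param type rule type for [read_label_map()]: `"prefix"` or
#'   `"statement"`.
#' @return `write_label_map()` returns `path` invisibly; `read_label_map()`
#'   returns a `label_map`.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  utils::write.csv(map$rules[, c("pattern", "class")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path, type = c("prefix", "statement")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  label_map(df, type = match.arg(type))
}

#' Map ICD-10 codes to a target class
#'
#' Codes are normalized (trimmed, upper-cased, dot retained) and matched
#' against the map's prefix rules, longest prefix first. Records whose codes
#' match rules of two different target classes are ambiguous and excluded
#' (`NA`) under the default policy.
#'
#' @param codes character vector of ICD-10 codes for one record.
#' @param map a `label_map` of type `"prefix"`.
#' @param ambiguous `"exclude"` (default: multi-class matches yield `NA`) or
#'   `"first"` (first matching code wins).
#' @return the target class, or `NA_character_` when no rule matches.
#' @export
map_codes <- function(codes, map, ambiguous = c("exclude", "first")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(inherits(map, "label_map"))
  if (!length(codes)) return(NA_character_)
  codes <- toupper(trimws(as.character(codes)))
  hit <- character(0)
  for (code in codes) {
    for (r in seq_len(nrow(map$rules))) {         # rules sorted longest-first
      if (startsWith(code, map$rules$pattern[r])) {
        hit <- c(hit, map$rules$class[r])
        break
      }
    }
  }
  hit <- unique(hit)
  if (!length(hit)) return(NA_character_)
  if (length(hit) > 1 && ambiguous == "exclude") return(NA_character_)
  hit[1]
}

#' Merge diagnostic statements into superclasses
#'
#' Exact-match statement harmonization, e.g. complete and incomplete right
#' bundle branch block both count as the superclass RBBB.
#'
#' @param statements character vector of statement ids.
#' @param map a `label_map` of type `"statement"` (default: the BBB merge).
#' @return character vector of merged labels (`NA` where unmapped).
#' @export
merge_superclasses <- function(statements, map = builtin_label_map("statement_bbb")) {
  stopifnot(inherits(map, "label_map"))
  s <- toupper(trimws(as.character(statements)))
  idx <- match(s, map$rules$pattern)
  out <- map$rules$class[idx]
  out
}

#' Deduplicate records per patient
#'
#' @param manifest a `dataset_manifest` (see [read_manifest()]).
#' @param policy `"first"` keeps the earliest `acquired_at` per patient (ties
#'   broken by `record_path`); `"only_one"` keeps one deterministic record
#'   per patient (first by `record_path`), intended for use before any
#'   stratified split.
#' @return the filtered manifest, one row per `patient_id`.
#' @export
dedup_patients <- function(manifest, policy = c("first", "only_one")) {
  policy <- match.arg(policy)
  df <- as.data.frame(manifest)
  if (policy == "first") {
    if (is.null(df$acquired_at) || anyNA(df$acquired_at)) {
      warning("no usable acquired_at; falling back to record order")
      o <- order(df$patient_id, df$record_path)
    } else {
      o <- order(df$patient_id, df$acquired_at, df$record_path)
    }
  } else {
    o <- order(df$patient_id, df$record_path)
  }
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, classes = sort(unique(as.character(df$label))),
            class = c("dataset_manifest", "data.frame"))
}
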