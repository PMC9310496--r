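#' Declare a column schema for a patient table
#'
#' @param kinds Named character vector or list mapping column names to one of
#'   `"date"`, `"continuous"`, `"ordinal"`, `"categorical"`, `"binary"`.
#' @param required Character vector of column names whose absence in a record
#'   excludes it from analysis.
#' @return A `patient_schema` list.
#' @export
patient_schema <- function(kinds, required = character()) {
  kinds <- unlist(kinds)
  valid <- c("date", "continuous", "ordinal", "categorical", "binary")
  if (is.null(names(kinds)) || any(names(kinds) == "")) {
    abort("Every schema entry must be named by its column.",
          class = "efsemble_error_schema")
  }
  bad <- setdiff(unique(kinds), valid)
  if (length(bad)) {
    abort(paste0("Unknown column kind(s): ", paste(bad, collapse = ", ")),
          class = "efsemble_error_schema")
  }
  structure(list(kinds = kinds, required = required),
            class = "patient_schema")
}

#' Read a patient schema from a YAML or JSON file
#'
#' The file holds two top-level keys: `columns` (name -> kind) and
#' `required` (list of names).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A `patient_schema` list.
#' @export
read_patient_schema <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  patient_schema(spec$columns, required = spec$required %||% character())
}

#' Read a raw patient table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row; missing values are
#' encoded as empty strings or `NA`. Declared date columns are parsed as
#' ISO-8601 or DD/MM/YYYY; continuous and ordinal columns as numeric; other
#' columns are carried through as character. Columns absent from the schema
#' are kept and treated as categorical.
#'
#' @param path Path to the CSV file.
#' @param schema A [patient_schema()]; may be `NULL` to accept all columns
#'   as-is.
#' @return A tibble with attribute `schema`.
#' @export
read_patient_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "efsemble_error_format")
  }
  header <- readr::read_lines(path, n_max = 1)
  if (length(header) == 0 || !nzchar(header)) {
    abort("Empty file: no header row.", class = "efsemble_error_format")
  }
  header_names <- strsplit(header, ",", fixed = TRUE)[[1]]
  header_names <- gsub("^\"|\"$", "", trimws(header_names))
  if (anyDuplicated(header_names)) {
    abort(paste0("Duplicated column name(s): ",
                 paste(unique(header_names[duplicated(header_names)]),
                       collapse = ", ")),
          class = "efsemble_error_schema")
  }
  raw <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    missing_cols <- setdiff(names(schema$kinds), names(raw))
    if (length(missing_cols)) {
      abort(paste0("Declared column(s) missing from file: ",
                   paste(missing_cols, collapse = ", ")),
            class = "efsemble_error_schema")
    }
    for (col in names(schema$kinds)) {
      raw[[col]] <- switch(
        schema$kinds[[col]],
        date = parse_clinic_date(raw[[col]]),
        continuous = ,
        ordinal = as.numeric(raw[[col]]),
        binary = ,
        categorical = raw[[col]]
      )
    }
  }
  attr(raw, "schema") <- schema
  attr(raw, "source_path") <- path
  raw
}

parse_clinic_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[which(iso)] <- as.Date(x[which(iso)])
  out[which(dmy)] <- as.Date(x[which(dmy)], format = "%d/%m/%Y")
  bad <- !is.na(x) & !iso & !dmy
  if (any(bad)) {
    abort(paste0("Unparseable date value(s), e.g. \"", x[which(bad)[1]],
                 "\"; expected ISO-8601 or DD/MM/YYYY."),
          class = "efsemble_error_format")
  }
  out
}

#' Drop records with missing required fields
#'
#' Mirrors the complete-case policy used in clinic cohorts: a record missing
#' any required column is excluded; retained rows are untouched. The number
#' excluded is recorded in the `n_excluded` attribute and reported.
#'
#' @param data A patient tibble.
#' @param required Character vector of required columns; defaults to the
#'   `required` set of the table's schema attribute.
#' @param quiet Suppress the exclusion message.
#' @return The filtered tibble with attributes `n_excluded` and `n_input`.
#' @export
exclude_incomplete <- function(data, required = NULL, quiet = FALSE) {
  schema <- attr(data, "schema")
  required <- required %||% schema$required
  if (is.null(required) || length(required) == 0) {
    abort("No required columns declared.", class = "efsemble_error_schema")
  }
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("Required column(s) absent: ",
                 paste(missing_cols, collapse = ", ")),
          class = "efsemble_error_schema")
  }
  keep <- !Reduce(`|`, lapply(data[required], is.na))
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("All records excluded: no complete cases.",
          class = "efsemble_error_degenerate")
  }
  if (!quiet) {
    message(sum(!keep), " of ", nrow(data),
            " records excluded for incomplete data.")
  }
  attr(out, "schema") <- schema
  attr(out, "n_input") <- nrow(data)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Derive engineered clinical variables
#'
#' Adds the analysis variables used in lymphedema risk modelling and removes
#' their raw sources:
#' * `age` — whole years (floor) between `date_of_birth` and
#'   `diagnosis_date`; an existing `age` column is accepted verbatim.
#' * `bmi` — `weight` (kg) divided by squared `height` (m); replaces the
#'   height and weight columns. Heights recorded in centimetres (values
#'   above 3) are converted to metres first.
#' * `node_ratio` — involved lymph nodes over removed lymph nodes. A removed
#'   count of zero leaves the ratio undefined (`NA`): such rows fall to the
#'   required-column exclusion step rather than receiving an invented value.
#'
#' Date-of-birth and referral-date columns are dropped. The function is
#' idempotent: once a derived column exists and its sources are gone, a
#' second application changes nothing.
#'
#' @param data A patient tibble.
#' @return The tibble with derived columns, source columns removed.
#' @export
derive_features <- function(data) {
  schema <- attr(data, "schema")
  if (!"age" %in% names(data) &&
      all(c("date_of_birth", "diagnosis_date") %in% names(data))) {
    data$age <- floor(as.numeric(
      difftime(data$diagnosis_date, data$date_of_birth, units = "days")
    ) / 365.25)
  }
  if (!"bmi" %in% names(data) &&
      all(c("height", "weight") %in% names(data))) {
    height <- as.numeric(data$height)
    if (any(!is.na(height) & height <= 0)) {
      abort("Nonpositive height encountered.", class = "efsemble_error_value")
    }
    height <- ifelse(!is.na(height) & height > 3, height / 100, height)
    data$bmi <- as.numeric(data$weight) / height^2
  }
  if (!"node_ratio" %in% names(data) &&
      all(c("nodes_involved", "nodes_removed") %in% names(data))) {
    removed <- as.numeric(data$nodes_removed)
    data$node_ratio <- ifelse(
      !is.na(removed) & removed == 0,
      NA_real_,
      as.numeric(data$nodes_involved) / removed
    )
  }
  drop <- intersect(
    c("date_of_birth", "referral_date", "height", "weight"),
    names(data)
  )
  out <- data[setdiff(names(data), drop)]
  attr(out, "schema") <- schema
  out
}

#' Encode dominant-hand / involved-side alignment
#'
#' Codes whether the involved limb is on the patient's dominant side. Both
#' conventions are supported so that the coding itself can be flipped between
#' repeat runs: under `"aligned_is_zero"` alignment codes 0 and
#' non-alignment 1; `"aligned_is_one"` reverses this.
#'
#' @param dominant_hand,involved_side Character vectors of side tokens
#'   (`"left"`/`"right"`, case-insensitive, `"l"`/`"r"` accepted).
#' @param coding `"aligned_is_zero"` (default) or `"aligned_is_one"`.
#' @return Integer vector of 0/1 codes.
#' @examples
#' encode_alignment("right", "right")                      # 0
#' encode_alignment("right", "left")                       # 1
#' encode_alignment("right", "right", "aligned_is_one")    # 1
#' @export
encode_alignment <- function(dominant_hand, involved_side,
                             coding = c("aligned_is_zero", "aligned_is_one")) {
  coding <- match.arg(coding)
  norm <- function(x) {
    x <- tolower(trimws(as.character(x)))
    x[x == "l"] <- "left"
    x[x == "r"] <- "right"
    bad <- !is.na(x) & !x %in% c("left", "right")
    if (any(bad)) {
      abort(paste0("Unknown side token: \"", x[which(bad)[1]], "\""),
            class = "efsemble_error_value")
    }
    x
  }
  aligned <- norm(dominant_hand) == norm(involved_side)
  if (coding == "aligned_is_zero") as.integer(!aligned) else as.integer(aligned)
}

#' Assign the binary lymphedema label from edema volume
#'
#' A record is labelled 1 (lymphedema) iff its edema volume is strictly
#' greater than the threshold; a volume exactly at the threshold is class 0.
#'
#' @param edema_volume_ml Numeric vector of volumes in millilitres (>= 0).
#' @param threshold_ml Decision threshold in millilitres, default 200.
#' @return Integer vector of 0/1 labels.
#' @examples
#' assign_label(c(350, 200, 0))  # 1 0 0
#' @export
assign_label <- function(edema_volume_ml, threshold_ml = 200) {
  if (threshold_ml <= 0) {
    abort("`threshold_ml` must be positive.", class = "efsemble_error_config")
  }
  v <- as.numeric(edema_volume_ml)
  if (any(!is.na(v) & v < 0)) {
    abort("Negative edema volume encountered.", class = "efsemble_error_value")
  }
  as.integer(!is.na(v) & v > threshold_ml)
}

#' Finalise a patient table into a numeric feature table
#'
#' Produces the modelling table: every feature numeric, a 0/1 `class` column,
#' and (optionally) the minority class replicated to soften imbalance.
#'
#' Character/factor columns are integer-coded from 0 with levels in
#' lexicographic order; the mapping is stored in the `encodings` attribute so
#' codes can be inverted. If `class` is absent it is derived from
#' `edema_volume_ml` via [assign_label()], and the volume column is then
#' dropped (it defines the label and must not leak into the features).
#' Replication appends `balance_factor - 1` extra copies of every
#' minority-class row after encoding.
#'
#' @param data A patient tibble with derived features.
#' @param balance_factor Positive integer; 1 (default) leaves classes as-is,
#'   3 reproduces the 230 -> 690 minority replication implied by benchmark
#'   confusion totals of 690/740.
#' @param edema_threshold_ml Labelling threshold passed to [assign_label()].
#' @param drop Extra columns to exclude from the feature set (identifiers,
#'   free text).
#' @return A tibble of numeric features plus `class`, with attributes
#'   `encodings` (named list of level vectors) and `class_counts`.
#' @export
finalize_features <- function(data, balance_factor = 1,
                              edema_threshold_ml = 200, drop = character()) {
  if (balance_factor < 1 || balance_factor != round(balance_factor)) {
    abort("`balance_factor` must be a positive integer.",
          class = "efsemble_error_config")
  }
  data <- data[setdiff(names(data), drop)]
  if (!"class" %in% names(data)) {
    if (!"edema_volume_ml" %in% names(data)) {
      abort("Need a `class` column or `edema_volume_ml` to derive it.",
            class = "efsemble_error_schema")
    }
    data$class <- assign_label(data$edema_volume_ml, edema_threshold_ml)
  }
  data <- data[setdiff(names(data), "edema_volume_ml")]
  if (length(unique(data$class)) < 2) {
    abort("Degenerate cohort: only one class present.",
          class = "efsemble_error_degenerate")
  }

  encodings <- list()
  for (col in setdiff(names(data), "class")) {
    v <- data[[col]]
    if (inherits(v, "Date")) {
      data[[col]] <- as.numeric(v)
    } else if (is.character(v) || is.factor(v) || is.logical(v)) {
      levels <- sort(unique(as.character(v[!is.na(v)])))
      encodings[[col]] <- levels
      data[[col]] <- match(as.character(v), levels) - 1L
    } else {
      data[[col]] <- as.numeric(v)
    }
  }

  if (anyNA(data)) {
    abort("Feature table contains missing values; run exclude_incomplete() first.",
          class = "efsemble_error_value")
  }

  if (balance_factor > 1) {
    counts <- table(data$class)
    minority <- as.integer(names(counts)[which.min(counts)])
    extra <- data[rep(which(data$class == minority), balance_factor - 1), ,
                  drop = FALSE]
    data <- dplyr::bind_rows(data, extra)
  }

  out <- as_tibble(data)
  attr(out, "encodings") <- encodings
  attr(out, "class_counts") <- c(
    `0` = sum(out$class == 0),
    `1` = sum(out$class == 1)
  )
  out
}

#' Invert a stored categorical encoding
#'
#' @param codes Integer codes produced by [finalize_features()].
#' @param levels The level vector stored in the table's `encodings` attribute.
#' @return Character vector of original levels.
#' @export
decode_levels <- function(codes, levels) {
  levels[codes + 1L]
}

#' Write a feature table with its encoding sidecar
#'
#' Writes the encoded table as CSV and a JSON sidecar recording categorical
#' encodings and class counts, so a downstream run can reproduce the coding.
#'
#' @param data A finalised feature table.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path) {
  readr::write_csv(data, path)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(
      encodings = attr(data, "encodings") %||% list(),
      class_counts = as.list(attr(data, "class_counts")),
      n_rows = nrow(data)
    ),
    sidecar, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
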