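# Synthetic multimodal EHR cohorts with the statistical shape of ICU data:
# rare positive outcomes, mixed numeric/binary structured features with
# missingness, and multiple note types whose token content carries class
# signal partially complementary to the structured signal.  Also implements
# the preprocessing pipeline: missingness filter, one-hot encoding,
# train-fitted normalization and imputation, and note prefixing/concatenation/
# tokenization to a fixed 512-token length.

NOTE_TYPE_ORDER <- c("Nursing", "Nursing/Other", "Physician", "Radiology")

INFORMATIVE_TOKENS <- c("deteriorating", "unresponsive", "sepsis", "hypotension",
                        "intubated", "vasopressors", "desaturation", "obtunded",
                        "bradycardia", "oliguria", "acidosis", "agitated")

#' Synthetic cohort specification
#'
#' Describes the study conditions the generator emulates: outcome prevalence
#' around 12% (ICU mortality / prolonged-stay range), class-conditional
#' Gaussian numeric features and Bernoulli binary features with a missing-
#' completely-at-random mechanism, and per-note-type token streams where
#' class-informative tokens appear at class-dependent rates.  A fraction of
#' the discriminative signal is shared between the two modalities; the rest is
#' complementary (each positive patient expresses signal in both, only the
#' structured, or only the notes modality), and a small fraction of positives
#' express only attenuated signal so the cohort has genuinely borderline
#' cases.
#'
#' @param n_patients Cohort size.
#' @param positive_rate Outcome prevalence (default 0.12).
#' @param n_numeric,n_binary Numbers of numeric and binary structured features.
#' @param n_informative_numeric,n_informative_binary How many of them carry
#'   class signal.
#' @param effect_numeric Mean shift (in SD units) of informative numeric
#'   features for signal-expressing positives.
#' @param effect_binary Rate shift of informative binary features.
#' @param weak_fraction Fraction of positives expressing only weak signal.
#' @param weak_multiplier Effect multiplier for weak-signal positives.
#' @param missing_rate MCAR missingness rate per structured cell.
#' @param modality_correlation Fraction of positives expressing signal in both
#'   modalities; the remainder split evenly between structured-only and
#'   notes-only.
#' @param note_types Subset of Nursing, Nursing/Other, Physician, Radiology.
#' @param vocab_size Background vocabulary size.
#' @param n_informative_tokens Number of class-informative tokens (max 12).
#' @param token_rate_pos,token_rate_neg Per-note appearance probability of each
#'   informative token for signal-expressing positives vs everyone else.
#' @param note_length Background tokens per note.
#' @param task `"mortality"` (direct binary label) or `"plos"` (label derived
#'   from a generated length of stay via the >7-day rule).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1000L, positive_rate = 0.12,
                        n_numeric = 20L, n_binary = 10L,
                        n_informative_numeric = 6L, n_informative_binary = 4L,
                        effect_numeric = 1.2, effect_binary = 0.25,
                        weak_fraction = 0.15, weak_multiplier = 0.4,
                        missing_rate = 0.10, modality_correlation = 0.5,
                        note_types = NOTE_TYPE_ORDER, vocab_size = 120L,
                        n_informative_tokens = 12L, token_rate_pos = 0.25,
                        token_rate_neg = 0.02, note_length = 30L,
                        task = c("mortality", "plos"), seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_patients >= 1L, positive_rate >= 0, positive_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            modality_correlation >= 0, modality_correlation <= 1,
            n_informative_numeric <= n_numeric,
            n_informative_binary <= n_binary,
            n_informative_tokens <= length(INFORMATIVE_TOKENS),
            all(note_types %in% NOTE_TYPE_ORDER))
  if (n_numeric + n_binary == 0L) stop("need at least one structured feature")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic multimodal cohort
#'
#' Fully seeded: the same spec always yields byte-identical output.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: `structured` (data frame of features,
#'   with NA for missing cells), `col_tags` (name/source/type per column),
#'   `notes` (patient_id, note_type, text records), `labels` (0/1),
#'   `patient_id`, `los_days` (for the plos task), and `frame`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$effect_numeric == 0 && spec$effect_binary == 0 &&
      spec$token_rate_pos < spec$token_rate_neg)
    stop("spec carries negative signal everywhere; nothing to generate")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_patients
  los <- NULL
  if (spec$task == "plos") {
    is_pos <- stats::rbinom(n, 1L, spec$positive_rate)
    los <- ifelse(is_pos == 1L, 7 + stats::rgamma(n, shape = 2, scale = 3),
                  stats::runif(n, 0.25, 7))
    labels <- label_plos(los)
  } else {
    labels <- stats::rbinom(n, 1L, spec$positive_rate)
  }
  pos <- labels == 1L
  channel <- rep("none", n)
  rho <- spec$modality_correlation
  channel[pos] <- sample(c("both", "structured", "notes"), sum(pos),
                         replace = TRUE,
                         prob = c(rho, (1 - rho) / 2, (1 - rho) / 2))
  strength <- rep(0, n)
  strength[pos] <- ifelse(stats::runif(sum(pos)) < spec$weak_fraction,
                          spec$weak_multiplier, 1)
  s_signal <- strength * (channel %in% c("both", "structured"))
  n_signal <- strength * (channel %in% c("both", "notes"))

  num <- matrix(stats::rnorm(n * spec$n_numeric), n, spec$n_numeric)
  if (spec$n_informative_numeric > 0L)
    for (j in seq_len(spec$n_informative_numeric))
      num[, j] <- num[, j] + s_signal * spec$effect_numeric
  bin <- matrix(0L, n, spec$n_binary)
  if (spec$n_binary > 0L) {
    base_rate <- 0.3
    for (j in seq_len(spec$n_binary)) {
      rate <- rep(base_rate, n)
      if (j <= spec$n_informative_binary)
        rate <- pmin(rate + s_signal * spec$effect_binary, 0.95)
      bin[, j] <- stats::rbinom(n, 1L, rate)
    }
  }
  structured <- as.data.frame(cbind(num, bin))
  names(structured) <- c(sprintf("num%02d", seq_len(spec$n_numeric)),
                         sprintf("bin%02d", seq_len(spec$n_binary)))[
                           seq_len(ncol(structured))]
  # MCAR missingness
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(n * ncol(structured)) < spec$missing_rate,
                   n, ncol(structured))
    for (j in seq_len(ncol(structured))) structured[mask[, j], j] <- NA
  }
  # source/type tags: numerics split demographics / vitals+labs, binaries
  # split treatments / comorbidities
  src_num <- rep("vitals_labs", spec$n_numeric)
  if (spec$n_numeric > 0L) src_num[seq_len(min(3L, spec$n_numeric))] <- "demographics"
  src_bin <- rep("comorbidities", spec$n_binary)
  if (spec$n_binary > 0L) src_bin[seq_len(ceiling(spec$n_binary / 2))] <- "treatments"
  col_tags <- data.frame(
    name = names(structured),
    source = c(src_num, src_bin)[seq_len(ncol(structured))],
    type = c(rep("numerical", spec$n_numeric),
             rep("categorical", spec$n_binary))[seq_len(ncol(structured))],
    stringsAsFactors = FALSE)

  patient_id <- sprintf("P%05d", seq_len(n))
  vocab <- sprintf("w%03d", seq_len(spec$vocab_size))
  info_tok <- INFORMATIVE_TOKENS[seq_len(spec$n_informative_tokens)]
  recs <- vector("list", n * length(spec$note_types))
  r <- 0L
  for (i in seq_len(n)) {
    for (nt in spec$note_types) {
      toks <- sample(vocab, spec$note_length, replace = TRUE)
      rate <- spec$token_rate_neg + n_signal[i] *
        (spec$token_rate_pos - spec$token_rate_neg)
      hit <- stats::runif(length(info_tok)) < rate
      if (any(hit)) {
        toks <- c(toks, info_tok[hit])
        toks <- sample(toks)
      }
      r <- r + 1L
      recs[[r]] <- data.frame(patient_id = patient_id[i], note_type = nt,
                              text = paste(toks, collapse = " "),
                              stringsAsFactors = FALSE)
    }
  }
  notes <- do.call(rbind, recs)
  structure(list(structured = structured, col_tags = col_tags, notes = notes,
                 labels = labels, patient_id = patient_id, los_days = los,
                 frame = ds_frame(c("negative", "positive")), spec = spec),
            class = "cohort")
}

#' Prolonged-length-of-stay labels
#'
#' A stay is prolonged iff it strictly exceeds 7 days.
#'
#' @param lengths_of_stay_days Non-negative stay durations in days.
#' @return Integer 0/1 labels.
#' @export
#' @examples
#' label_plos(c(1, 8, 7, 30))
label_plos <- function(lengths_of_stay_days) {
  stopifnot(all(lengths_of_stay_days >= 0, na.rm = TRUE))
  as.integer(lengths_of_stay_days > 7)
}

col_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tb <- table(x)
  nm <- names(tb)[which.max(tb)]
  if (is.numeric(x)) as.numeric(nm) else nm
}

#' Preprocess a structured table into a model-ready matrix
#'
#' Applies the structured-data pipeline: drops features with >= 50% missing
#' cells, one-hot encodes categorical features, imputes the median
#' (continuous) or mode (categorical), and z-normalizes continuous features.
#' All statistics — including the missingness filter — are computed on the
#' training rows only, so no information leaks from validation or test rows.
#'
#' @param table Data frame of raw features (NA = missing).
#' @param tags Data frame with `name`, `source`, `type` per column (columns of
#'   unknown type are inferred: numeric = numerical, otherwise categorical).
#' @param train_idx Rows used to fit statistics.
#' @param missing_cutoff Drop features with at least this training missing
#'   fraction (default 0.5).
#' @return List with `matrix` (all rows, transformed), `dropped` column names,
#'   `stats` (per-column centers/scales/imputes) and `col_tags` of the kept
#'   output columns.
#' @export
preprocess_structured <- function(table, tags = NULL,
                                  train_idx = seq_len(nrow(table)),
                                  missing_cutoff = 0.5) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  if (is.null(tags)) {
    # untagged columns: numeric columns with more than two distinct values are
    # continuous; everything else (characters, factors, 0/1 indicators) is
    # categorical
    infer <- vapply(table, function(x)
      is.numeric(x) && length(unique(x[!is.na(x)])) > 2L, TRUE)
    tags <- data.frame(name = names(table),
                       source = "unknown",
                       type = ifelse(infer, "numerical", "categorical"),
                       stringsAsFactors = FALSE)
  }
  miss_frac <- vapply(table[train_idx, , drop = FALSE],
                      function(x) mean(is.na(x)), 0)
  dropped <- names(table)[miss_frac >= missing_cutoff]
  kept <- setdiff(names(table), dropped)
  cols <- list(); out_tags <- list(); stats <- list()
  for (nm in kept) {
    x <- table[[nm]]
    tg <- tags[match(nm, tags$name), ]
    type <- if (!is.na(tg$type)) tg$type else if (is.numeric(x)) "numerical" else "categorical"
    if (type == "numerical") {
      med <- stats::median(x[train_idx], na.rm = TRUE)
      x[is.na(x)] <- med
      mu <- mean(x[train_idx]); sdv <- stats::sd(x[train_idx])
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      cols[[nm]] <- (x - mu) / sdv
      out_tags[[nm]] <- data.frame(name = nm, source = tg$source,
                                   type = "numerical")
      stats[[nm]] <- list(impute = med, center = mu, scale = sdv)
    } else {
      mode_val <- col_mode(x[train_idx])
      x[is.na(x)] <- mode_val
      lv <- sort(unique(as.character(x[train_idx])))
      if (is.numeric(table[[nm]]) && length(lv) <= 2L) {
        cols[[nm]] <- as.numeric(x)  # binary indicator stays a single column
        out_tags[[nm]] <- data.frame(name = nm, source = tg$source,
                                     type = "categorical")
      } else {
        for (l in lv) {
          cn <- paste0(nm, "=", l)
          cols[[cn]] <- as.numeric(as.character(x) == l)
          out_tags[[cn]] <- data.frame(name = cn, source = tg$source,
                                       type = "categorical")
        }
      }
      stats[[nm]] <- list(impute = mode_val, levels = lv)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- NULL
  list(matrix = mat, dropped = dropped, stats = stats,
       col_tags = do.call(rbind, unname(out_tags)))
}

#' Impute missing numeric values
#'
#' Four strategies for continuous features, all fitted on the training rows
#' only: mean, median, k-nearest-neighbour (k = 5, Euclidean distance over the
#' mutually observed columns, averaging the neighbours' values; donors at
#' distance zero — exact duplicates — take precedence), and iterative
#' (round-robin linear regressions per column until the largest imputed-value
#' change falls below 1e-3 or 10 rounds).
#'
#' @param table Data frame; only numeric columns are imputed.
#' @param strategy `"mean"`, `"median"`, `"knn"` or `"iterative"`.
#' @param train_idx Rows used to fit the imputation.
#' @param k Neighbours for the knn strategy.
#' @return The table with numeric missing cells filled.
#' @export
impute_missing <- function(table, strategy = c("mean", "median", "knn", "iterative"),
                           train_idx = seq_len(nrow(table)), k = 5L) {
  strategy <- match.arg(strategy)
  num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
  if (!length(num_cols) || !anyNA(table[num_cols])) return(table)
  X <- as.matrix(table[num_cols])
  obs <- !is.na(X)
  Xtr <- X[train_idx, , drop = FALSE]
  if (strategy %in% c("mean", "median")) {
    f <- if (strategy == "mean") mean else stats::median
    for (j in seq_len(ncol(X))) {
      v <- f(Xtr[, j], na.rm = TRUE)
      X[!obs[, j], j] <- v
    }
  } else if (strategy == "knn") {
    for (i in which(rowSums(!obs) > 0L)) {
      for (j in which(!obs[i, ])) {
        donors <- train_idx[!is.na(X[train_idx, j]) & train_idx != i]
        if (!length(donors)) { X[i, j] <- mean(Xtr[, j], na.rm = TRUE); next }
        shared <- obs[i, , drop = TRUE]
        d <- vapply(donors, function(dn) {
          both <- shared & obs[dn, ]
          both[j] <- FALSE
          if (!any(both)) return(Inf)
          mean((X[i, both] - X[dn, both])^2)
        }, 0)
        exact <- donors[d == 0]
        sel <- if (length(exact)) exact else donors[order(d)][seq_len(min(k, length(donors)))]
        X[i, j] <- mean(X[sel, j])
      }
    }
  } else {  # iterative
    fill <- colMeans(Xtr, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[!obs[, j], j] <- fill[j]
    in_train <- seq_len(nrow(X)) %in% train_idx
    for (round in seq_len(10L)) {
      max_change <- 0
      for (j in which(colSums(!obs) > 0L)) {
        fit_rows <- intersect(train_idx, which(obs[, j]))
        if (length(fit_rows) < 2L) next
        Z <- cbind(1, X[, -j, drop = FALSE])
        cf <- stats::lm.fit(Z[fit_rows, , drop = FALSE], X[fit_rows, j])$coefficients
        cf[is.na(cf)] <- 0
        pred <- as.vector(Z %*% cf)
        # convergence tracked on training cells only, so held-out rows cannot
        # influence how many refinement rounds the training fit receives
        tr_miss <- !obs[, j] & in_train
        if (any(tr_miss))
          max_change <- max(max_change, max(abs(pred[tr_miss] - X[tr_miss, j])))
        X[!obs[, j], j] <- pred[!obs[, j]]
      }
      if (max_change < 1e-3) break
    }
  }
  for (nm in num_cols) table[[nm]] <- X[, nm]
  table
}

default_tokenizer <- function(text) {
  strsplit(tolower(trimws(text)), "\\s+")[[1]]
}

#' Preprocess free-text notes into fixed-length token sequences
#'
#' Each note is prefixed with its type (`"Nursing: ..."`), a patient's notes
#' are concatenated with newlines in the fixed order Nursing, Nursing/Other,
#' Physician, Radiology, tokenized (default: lowercase whitespace), and
#' truncated or right-padded with `"<pad>"` to exactly `max_tokens` tokens.
#' Patients without notes yield all-padding sequences.
#'
#' @param records Data frame with `patient_id`, `note_type`, `text`.
#' @param patient_ids Patients to produce sequences for (default: those seen
#'   in `records`).
#' @param max_tokens Fixed sequence length (default 512).
#' @param tokenizer Function text -> character vector of tokens.
#' @return List with `text` (named concatenated strings) and `tokens` (named
#'   list of length-`max_tokens` token vectors).
#' @export
preprocess_notes <- function(records, patient_ids = NULL, max_tokens = 512L,
                             tokenizer = default_tokenizer) {
  if (is.null(patient_ids)) patient_ids <- unique(records$patient_id)
  texts <- stats::setNames(character(length(patient_ids)), patient_ids)
  tokens <- stats::setNames(vector("list", length(patient_ids)), patient_ids)
  ord <- order(match(records$note_type, NOTE_TYPE_ORDER))
  records <- records[ord, , drop = FALSE]
  by_patient <- split(records, factor(records$patient_id, levels = patient_ids))
  for (i in seq_along(patient_ids)) {
    recs <- by_patient[[i]]
    if (is.null(recs) || nrow(recs) == 0L) {
      texts[i] <- ""
      tokens[[i]] <- rep("<pad>", max_tokens)
      next
    }
    joined <- paste(paste0(recs$note_type, ": ", recs$text), collapse = "\n")
    texts[i] <- joined
    tk <- tokenizer(joined)
    if (length(tk) >= max_tokens) tk <- tk[seq_len(max_tokens)]
    else tk <- c(tk, rep("<pad>", max_tokens - length(tk)))
    tokens[[i]] <- tk
  }
  list(text = texts, tokens = tokens)
}

#' Write and read a cohort as plain-text files
#'
#' The canonical pipeline input formats: structured features as CSV (with the
#' patient id), column tags as a JSON sidecar, notes as JSONL, labels as CSV.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns the directory; `read_cohort`
#'   returns a `cohort` object.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(patient_id = cohort$patient_id, cohort$structured),
                   file.path(dir, "structured.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(cohort$col_tags, dataframe = "rows", digits = NA),
             file.path(dir, "col_tags.json"))
  con <- file(file.path(dir, "notes.jsonl"), "w")
  for (i in seq_len(nrow(cohort$notes)))
    writeLines(jsonlite::toJSON(as.list(cohort$notes[i, ]), auto_unbox = TRUE),
               con)
  close(con)
  lab <- data.frame(patient_id = cohort$patient_id, label = cohort$labels)
  if (!is.null(cohort$los_days)) lab$los_days <- cohort$los_days
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  stru <- utils::read.csv(file.path(dir, "structured.csv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  tags <- jsonlite::fromJSON(file.path(dir, "col_tags.json"))
  lines <- readLines(file.path(dir, "notes.jsonl"))
  notes <- do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
  lab <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  structure(list(structured = stru[, setdiff(names(stru), "patient_id"),
                                   drop = FALSE],
                 col_tags = tags, notes = notes, labels = lab$label,
                 patient_id = stru$patient_id, los_days = lab$los_days,
                 frame = ds_frame(c("negative", "positive")), spec = NULL),
            class = "cohort")
}
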