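# Assembles per-modality encoders, evidential layers and auxiliary heads into
# the full fusion model: evidence mapping per modality, evidence fusion by
# Dempster's rule, pignistic decision output; plus the three comparison fusion
# strategies (concatenation, mean, attention) and the data-partitioning
# settings that control how inputs are split into evidence sources.

#' Fusion specification
#'
#' @param strategy `"evidential"` (Dempster-rule evidence fusion, the model of
#'   interest) or one of the comparison strategies `"concatenation"`, `"mean"`,
#'   `"attention"`.
#' @param partition How the raw data are split into evidence sources:
#'   `"modalities"` (structured vs notes), `"data_types"` (numerical,
#'   categorical, notes) or `"data_sources"` (demographics, vitals/labs,
#'   treatments, comorbidities and one bundle per note type).
#' @return An object of class `fusion_spec`.
#' @export
fusion_spec <- function(strategy = c("evidential", "concatenation", "mean", "attention"),
                        partition = c("modalities", "data_types", "data_sources")) {
  structure(list(strategy = match.arg(strategy),
                 partition = match.arg(partition)),
            class = "fusion_spec")
}

#' Modality bundle
#'
#' One evidence source: its encoder, its evidential (evidence-mapping) layer
#' and its auxiliary head.  The evidential layer must live in the encoder's
#' output space.
#'
#' @param name Bundle name.
#' @param encoder An [init_encoder()] or projection encoder.
#' @param em_layer A [prototype_bank()] (NULL for baseline strategies).
#' @param aux_head An [init_aux_head()] (NULL for baseline strategies).
#' @return An object of class `modality_bundle`.
#' @export
modality_bundle <- function(name, encoder, em_layer = NULL, aux_head = NULL) {
  if (!is.null(em_layer) &&
      ncol(em_layer$prototypes) != encoder$cfg$output_dim)
    stop("evidential layer dimension must equal encoder output dimension")
  structure(list(name = name, encoder = encoder, em_layer = em_layer,
                 aux_head = aux_head),
            class = "modality_bundle")
}

# single dense projection layer (used for text embeddings): affine + ReLU
init_projection_encoder <- function(input_dim, hidden_units = 128L, seed = 1L) {
  enc <- init_encoder(input_dim,
                      structured_encoder_config("mlp", n_layers = 1L,
                                                hidden_units = hidden_units,
                                                dropout = 0,
                                                output_dim = hidden_units),
                      seed = seed)
  enc$final_relu <- TRUE
  enc
}

#' Build a fusion model over prepared bundle inputs
#'
#' Initializes one modality bundle per input matrix: a tabular encoder
#' (MLP/ResNet) for structured bundles, a 128-unit projection for note-
#' embedding bundles, a prototype bank initialized from the encoded training
#' features, and an auxiliary head.  For baseline strategies the fusion
#' network (concatenation / mean / attention) is initialized instead of the
#' evidential layers.
#'
#' @param inputs Named list of N x d numeric matrices, one per bundle.
#' @param frame The outcome [ds_frame()]; the second label is treated as the
#'   positive class.
#' @param spec A [fusion_spec()].
#' @param kinds Character vector (per bundle): `"structured"` or `"notes"`.
#'   Defaults to the `"kinds"` attribute of `inputs`, else all structured.
#' @param architecture Tabular encoder architecture for structured bundles.
#' @param n_prototypes Prototypes per evidential layer (default 20).
#' @param train_idx Rows used to initialize prototypes (default all rows).
#' @param threshold Decision threshold on the pignistic positive probability.
#' @param seed Integer seed.
#' @return An object of class `fusion_model`.
#' @export
build_fusion_model <- function(inputs, frame, spec = fusion_spec(),
                               kinds = NULL, architecture = "mlp",
                               n_prototypes = 20L,
                               train_idx = seq_len(nrow(inputs[[1L]])),
                               threshold = 0.5, seed = 1L) {
  stopifnot(is.list(inputs), length(inputs) >= 1L, !is.null(names(inputs)))
  if (is.null(kinds)) kinds <- attr(inputs, "kinds")
  if (is.null(kinds)) kinds <- rep("structured", length(inputs))
  evidential <- spec$strategy == "evidential"
  bundles <- list()
  for (k in seq_along(inputs)) {
    nm <- names(inputs)[k]
    X <- inputs[[k]]
    enc <- if (kinds[k] == "notes") {
      init_projection_encoder(ncol(X), seed = seed + 31L * k)
    } else {
      init_encoder(ncol(X), structured_encoder_config(architecture),
                   seed = seed + 31L * k)
    }
    em <- NULL; aux <- NULL
    if (evidential) {
      feats <- encode_structured(X[train_idx, , drop = FALSE], enc)
      em <- init_prototype_bank(feats, frame,
                                em_config(n_prototypes,
                                          feature_dim = enc$cfg$output_dim),
                                seed = seed + 7L * k)
      aux <- init_aux_head(enc$cfg$output_dim, frame$M, seed = seed + 13L * k)
    }
    bundles[[nm]] <- modality_bundle(nm, enc, em, aux)
  }
  fusion_params <- NULL
  if (!evidential) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed + 97L)
    dims <- vapply(bundles, function(b) b$encoder$cfg$output_dim, 1L)
    pw <- 32L
    fusion_params <- switch(spec$strategy,
      concatenation = list(W1 = he_init(sum(dims), pw), b1 = matrix(0, 1L, pw),
                           W2 = he_init(pw, frame$M), b2 = matrix(0, 1L, frame$M)),
      mean = ,
      attention = {
        p <- list(W = he_init(pw, frame$M), b = matrix(0, 1L, frame$M))
        for (k in seq_along(bundles)) {
          p[[paste0("P", k)]] <- he_init(dims[k], pw)
          p[[paste0("pb", k)]] <- matrix(0, 1L, pw)
          if (spec$strategy == "attention") {
            p[[paste0("a", k)]] <- he_init(pw, 1L)
            p[[paste0("ac", k)]] <- matrix(0, 1L, 1L)
          }
        }
        p
      })
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  structure(list(bundles = bundles, spec = spec, frame = frame, kinds = kinds,
                 fusion_params = fusion_params, threshold = threshold,
                 positive_class = frame$M, seed = seed),
            class = "fusion_model")
}

# ---- parameter flattening ---------------------------------------------------

flatten_params <- function(model) {
  out <- list()
  for (k in seq_along(model$bundles)) {
    b <- model$bundles[[k]]
    for (nm in names(b$encoder$params))
      out[[paste0("b", k, ".enc.", nm)]] <- b$encoder$params[[nm]]
    if (!is.null(b$em_layer)) {
      out[[paste0("b", k, ".em.prototypes")]] <- b$em_layer$prototypes
      out[[paste0("b", k, ".em.raw_gamma")]] <- b$em_layer$raw_gamma
      out[[paste0("b", k, ".em.raw_beta")]] <- b$em_layer$raw_beta
      out[[paste0("b", k, ".em.raw_membership")]] <- b$em_layer$raw_membership
    }
    if (!is.null(b$aux_head))
      for (nm in names(b$aux_head$params))
        out[[paste0("b", k, ".aux.", nm)]] <- b$aux_head$params[[nm]]
  }
  for (nm in names(model$fusion_params))
    out[[paste0("fus.", nm)]] <- model$fusion_params[[nm]]
  out
}

set_params <- function(model, flat) {
  for (k in seq_along(model$bundles)) {
    b <- model$bundles[[k]]
    for (nm in names(b$encoder$params))
      model$bundles[[k]]$encoder$params[[nm]] <- flat[[paste0("b", k, ".enc.", nm)]]
    if (!is.null(b$em_layer)) {
      model$bundles[[k]]$em_layer$prototypes <- flat[[paste0("b", k, ".em.prototypes")]]
      model$bundles[[k]]$em_layer$raw_gamma <- flat[[paste0("b", k, ".em.raw_gamma")]]
      model$bundles[[k]]$em_layer$raw_beta <- flat[[paste0("b", k, ".em.raw_beta")]]
      model$bundles[[k]]$em_layer$raw_membership <- flat[[paste0("b", k, ".em.raw_membership")]]
    }
    if (!is.null(b$aux_head))
      for (nm in names(b$aux_head$params))
        model$bundles[[k]]$aux_head$params[[nm]] <- flat[[paste0("b", k, ".aux.", nm)]]
  }
  for (nm in names(model$fusion_params))
    model$fusion_params[[nm]] <- flat[[paste0("fus.", nm)]]
  model
}

# ---- differentiable graphs --------------------------------------------------

LOG_EPS <- 1e-30

# evidential layer on the tape, using the closed-form product expression for
# the orthogonal sum of restricted masses (identical to the pairwise fold)
enn_graph <- function(tape, feat_id, pids, M) {
  D <- ad_sqdist(tape, feat_id, pids$prototypes)
  gam <- ad_softplus(tape, pids$raw_gamma)
  E <- ad_exp(tape, ad_smul(tape, ad_colscale(tape, D, gam), -1))
  bet <- ad_sigmoid(tape, pids$raw_beta)
  s <- ad_colscale(tape, E, bet)                            # N x H activations
  U <- ad_softmax_rows(tape, pids$raw_membership)           # H x M memberships
  log_ign <- ad_rowsum(tape, ad_log(tape, ad_clamp_min(
    tape, ad_csub(tape, 1, s), LOG_EPS)))                   # log prod_h (1-s_h)
  mu <- vector("list", M + 1L)
  ign <- ad_exp(tape, log_ign)
  for (c in seq_len(M)) {
    one_minus_uc <- ad_csub(tape, 1, ad_cols(tape, U, c))
    t <- ad_colscale(tape, s, one_minus_uc)                 # s_h (1 - u_h^c)
    logA <- ad_rowsum(tape, ad_log(tape, ad_clamp_min(
      tape, ad_csub(tape, 1, t), LOG_EPS)))
    mu[[c]] <- ad_sub(tape, ad_exp(tape, logA), ign)
  }
  mu[[M + 1L]] <- ign
  raw <- ad_cbind(tape, mu)
  z <- ad_clamp_min(tape, ad_rowsum(tape, raw), EPS_CONFLICT)
  ad_scale_rows(tape, raw, ad_recip(tape, z))
}

# Dempster fusion of K restricted-mass nodes (each N x (M+1))
fuse_graph <- function(tape, mass_ids, M) {
  if (length(mass_ids) == 1L) return(mass_ids[[1L]])
  prod_ign <- NULL
  prod_cls <- vector("list", M)
  for (mid in mass_ids) {
    w <- ad_cols(tape, mid, M + 1L)
    prod_ign <- if (is.null(prod_ign)) w else ad_mul(tape, prod_ign, w)
    for (c in seq_len(M)) {
      a <- ad_add(tape, ad_cols(tape, mid, c), w)
      prod_cls[[c]] <- if (mid == mass_ids[[1L]]) a else ad_mul(tape, prod_cls[[c]], a)
    }
  }
  mu <- lapply(seq_len(M), function(c) ad_sub(tape, prod_cls[[c]], prod_ign))
  raw <- ad_cbind(tape, c(mu, list(prod_ign)))
  z <- ad_clamp_min(tape, ad_rowsum(tape, raw), EPS_CONFLICT)
  ad_scale_rows(tape, raw, ad_recip(tape, z))
}

pignistic_graph <- function(tape, mass_id, M) {
  ign <- ad_smul(tape, ad_cols(tape, mass_id, M + 1L), 1 / M)
  ad_cbind(tape, lapply(seq_len(M), function(c)
    ad_add(tape, ad_cols(tape, mass_id, c), ign)))
}

# full model graph; returns node ids for everything downstream losses need
model_graph <- function(tape, model, inputs, pids, training = FALSE) {
  M <- model$frame$M
  feats <- list(); masses <- list(); aux <- list()
  for (k in seq_along(model$bundles)) {
    b <- model$bundles[[k]]
    nm <- b$name
    if (is.null(inputs[[nm]])) stop("missing input for modality '", nm, "'")
    x_id <- ad_input(tape, inputs[[nm]])
    f <- encoder_graph(tape, b$encoder, x_id, pids_subset(pids, k, "enc"),
                       training = training)
    feats[[nm]] <- f
    if (model$spec$strategy == "evidential") {
      masses[[nm]] <- enn_graph(tape, f, pids_subset(pids, k, "em"), M)
      ap <- pids_subset(pids, k, "aux")
      aux[[nm]] <- ad_add_bias(tape, ad_mm(tape, f, ap$W), ap$b)
    }
  }
  if (model$spec$strategy == "evidential") {
    fused <- fuse_graph(tape, unname(masses), M)
    p <- pignistic_graph(tape, fused, M)
    return(list(feats = feats, masses = masses, aux = aux,
                fused = fused, p = p))
  }
  fp <- pids_subset(pids, NULL, "fus")
  K <- length(feats)
  logits <- switch(model$spec$strategy,
    concatenation = {
      h <- ad_relu(tape, ad_add_bias(tape, ad_mm(
        tape, ad_cbind(tape, unname(feats)), fp$W1), fp$b1))
      ad_add_bias(tape, ad_mm(tape, h, fp$W2), fp$b2)
    },
    mean = {
      proj <- lapply(seq_len(K), function(k) ad_add_bias(
        tape, ad_mm(tape, feats[[k]], fp[[paste0("P", k)]]), fp[[paste0("pb", k)]]))
      avg <- ad_smul(tape, Reduce(function(a, b) ad_add(tape, a, b), proj), 1 / K)
      ad_add_bias(tape, ad_mm(tape, avg, fp$W), fp$b)
    },
    attention = {
      proj <- lapply(seq_len(K), function(k) ad_add_bias(
        tape, ad_mm(tape, feats[[k]], fp[[paste0("P", k)]]), fp[[paste0("pb", k)]]))
      scores <- ad_cbind(tape, lapply(seq_len(K), function(k) ad_add_bias(
        tape, ad_mm(tape, proj[[k]], fp[[paste0("a", k)]]), fp[[paste0("ac", k)]])))
      wts <- ad_softmax_rows(tape, scores)
      mix <- Reduce(function(a, b) ad_add(tape, a, b),
                    lapply(seq_len(K), function(k)
                      ad_scale_rows(tape, proj[[k]], ad_cols(tape, wts, k))))
      ad_add_bias(tape, ad_mm(tape, mix, fp$W), fp$b)
    })
  p <- ad_softmax_rows(tape, logits)
  list(feats = feats, logits = logits, p = p)
}

pids_subset <- function(pids, k, group) {
  prefix <- if (group == "fus") "fus." else paste0("b", k, ".", group, ".")
  keep <- startsWith(names(pids), prefix)
  out <- pids[keep]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  out
}

#' Evaluate the fusion model
#'
#' Deterministic evaluation-mode forward pass over full input matrices.
#'
#' @param model A [build_fusion_model()] object.
#' @param inputs Named list of input matrices matching the model's bundles.
#' @return For the evidential strategy: a list with `p` (N x M pignistic
#'   probabilities), `fused_mass` (N x (M+1)), per-bundle `masses` and
#'   `aux_logits`, and `uncertainty` (fused ignorance per sample).  For
#'   baseline strategies: `p` and `logits`.
#' @export
model_forward <- function(model, inputs) {
  tape <- tape_new()
  flat <- flatten_params(model)
  pids <- lapply(flat, function(v) ad_input(tape, v))
  g <- model_graph(tape, model, inputs, pids, training = FALSE)
  M <- model$frame$M
  if (model$spec$strategy == "evidential") {
    fused <- ad_value(tape, g$fused)
    colnames(fused) <- c(model$frame$labels, "Omega")
    list(p = ad_value(tape, g$p),
         fused_mass = fused,
         masses = lapply(g$masses, function(i) ad_value(tape, i)),
         aux_logits = lapply(g$aux, function(i) ad_value(tape, i)),
         uncertainty = fused[, M + 1L])
  } else {
    list(p = ad_value(tape, g$p), logits = ad_value(tape, g$logits))
  }
}

#' Fuse per-modality evidence with Dempster's rule
#'
#' @param masses Non-empty list of [simple_mass()] objects on a shared frame.
#' @return The fused [simple_mass()] (a single input passes through unchanged).
#' @export
fuse_evidence <- function(masses) {
  stopifnot(all(vapply(masses, inherits, TRUE, "simple_mass")))
  fuse_masses(masses)
}

#' Baseline fusion of per-bundle features
#'
#' Eager forward pass of a comparison fusion strategy given already-encoded
#' features: concatenation (two fully connected layers), mean of projected
#' features, or attention-weighted combination of projected features.
#'
#' @param features Named list of N x d feature matrices, one per bundle, in
#'   the model's bundle order.
#' @param model A baseline-strategy [build_fusion_model()].
#' @return N x M logit matrix.
#' @export
baseline_fusion <- function(features, model) {
  stopifnot(model$spec$strategy != "evidential")
  fp <- model$fusion_params
  K <- length(features)
  addb <- function(X, W, b) sweep(X %*% W, 2L, as.vector(b), "+")
  switch(model$spec$strategy,
    concatenation = {
      widths <- vapply(features, ncol, 1L)
      if (sum(widths) != nrow(fp$W1)) stop("feature widths do not match model")
      h <- pmax(addb(do.call(cbind, features), fp$W1, fp$b1), 0)
      addb(h, fp$W2, fp$b2)
    },
    mean = {
      proj <- lapply(seq_len(K), function(k)
        addb(features[[k]], fp[[paste0("P", k)]], fp[[paste0("pb", k)]]))
      addb(Reduce(`+`, proj) / K, fp$W, fp$b)
    },
    attention = {
      proj <- lapply(seq_len(K), function(k)
        addb(features[[k]], fp[[paste0("P", k)]], fp[[paste0("pb", k)]]))
      scores <- do.call(cbind, lapply(seq_len(K), function(k)
        addb(proj[[k]], fp[[paste0("a", k)]], fp[[paste0("ac", k)]])))
      w <- softmax_rows(scores)
      mix <- Reduce(`+`, lapply(seq_len(K), function(k) proj[[k]] * w[, k]))
      addb(mix, fp$W, fp$b)
    })
}

#' Split a cohort into evidence-source bundles
#'
#' Returns the bundle layout for a partitioning setting: which structured
#' columns and which note types belong to each evidence source.  Bundle inputs
#' are disjoint and jointly exhaustive over the cohort's columns.
#'
#' @param cohort A cohort as produced by [generate_cohort()] (needs
#'   `structured`, `col_tags` with source/type per column, and `notes`).
#' @param partition `"modalities"`, `"data_types"` or `"data_sources"`.
#' @return Named list of bundle specs, each `list(kind, columns, note_types)`.
#' @export
split_by_partition <- function(cohort, partition = c("modalities", "data_types",
                                                     "data_sources")) {
  partition <- match.arg(partition)
  tags <- cohort$col_tags
  cols <- colnames(cohort$structured)
  untagged <- setdiff(cols, tags$name)
  if (length(untagged))
    stop("untagged structured column(s): ", paste(untagged, collapse = ", "))
  note_types <- intersect(c("Nursing", "Nursing/Other", "Physician", "Radiology"),
                          unique(cohort$notes$note_type))
  bundle <- function(kind, columns = NULL, note_types = NULL)
    list(kind = kind, columns = columns, note_types = note_types)
  out <- switch(partition,
    modalities = list(
      structured = bundle("structured", cols),
      notes = bundle("notes", note_types = note_types)),
    data_types = list(
      numerical = bundle("structured", tags$name[tags$type == "numerical"]),
      categorical = bundle("structured", tags$name[tags$type == "categorical"]),
      notes = bundle("notes", note_types = note_types)),
    data_sources = {
      srcs <- c("demographics", "vitals_labs", "treatments", "comorbidities")
      b <- lapply(srcs, function(s) bundle("structured", tags$name[tags$source == s]))
      names(b) <- srcs
      b <- b[vapply(b, function(x) length(x$columns) > 0L, TRUE)]
      nb <- lapply(note_types, function(nt) bundle("notes", note_types = nt))
      names(nb) <- paste0("notes_", gsub("[^A-Za-z]", "_", note_types))
      c(b, nb)
    })
  out
}

#' Prepare model-ready bundle input matrices
#'
#' Applies the structured preprocessing pipeline (missingness filter, one-hot,
#' train-fitted normalization and imputation) to each structured bundle and the
#' note pipeline (prefix, concatenate, tokenize to 512 tokens, frozen
#' embedding) to each notes bundle.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param partition Partitioning setting, see [split_by_partition()].
#' @param train_idx Training rows used to fit preprocessing statistics.
#' @param text_dim Hashing-embedding width (default 256).
#' @param max_tokens Token length of the note sequences (default 512).
#' @return Named list of numeric matrices with a `"kinds"` attribute.
#' @export
prepare_bundle_inputs <- function(cohort, partition = "modalities",
                                  train_idx = seq_len(nrow(cohort$structured)),
                                  text_dim = 256L, max_tokens = 512L) {
  specs <- split_by_partition(cohort, partition)
  out <- list()
  kinds <- character(0)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (sp$kind == "structured") {
      tab <- cohort$structured[, sp$columns, drop = FALSE]
      tags <- cohort$col_tags[match(sp$columns, cohort$col_tags$name), ]
      pp <- preprocess_structured(tab, tags, train_idx)
      out[[nm]] <- pp$matrix
    } else {
      recs <- cohort$notes[cohort$notes$note_type %in% sp$note_types, ]
      toks <- preprocess_notes(recs, patient_ids = cohort$patient_id,
                               max_tokens = max_tokens)
      out[[nm]] <- hashing_stub(toks$tokens, dim = text_dim)
    }
    kinds <- c(kinds, sp$kind)
  }
  attr(out, "kinds") <- kinds
  out
}

#' Predict outcomes and evidence for new samples
#'
#' @param object A [build_fusion_model()] object.
#' @param inputs Named list of input matrices.
#' @param ids Optional sample identifiers.
#' @param ... Unused.
#' @return A data frame with one row per sample: `id`, `p_positive`, the fused
#'   singleton masses `m_pos` / `m_neg`, the fused ignorance `m_omega`, and
#'   `predicted_label` (1 if p_positive >= threshold).
#' @export
predict.fusion_model <- function(object, inputs, ids = NULL, ...) {
  fw <- model_forward(object, inputs)
  pos <- object$positive_class
  neg <- setdiff(seq_len(object$frame$M), pos)[1L]
  p_pos <- fw$p[, pos]
  n <- length(p_pos)
  if (is.null(ids)) ids <- seq_len(n)
  if (object$spec$strategy == "evidential") {
    data.frame(id = ids, p_positive = p_pos,
               m_pos = fw$fused_mass[, pos], m_neg = fw$fused_mass[, neg],
               m_omega = fw$fused_mass[, object$frame$M + 1L],
               predicted_label = as.integer(p_pos >= object$threshold))
  } else {
    data.frame(id = ids, p_positive = p_pos, m_pos = NA_real_, m_neg = NA_real_,
               m_omega = NA_real_,
               predicted_label = as.integer(p_pos >= object$threshold))
  }
}
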