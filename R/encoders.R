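# Per-modality feature extractors: tabular MLP and ResNet encoders, a
# pluggable slot for external tabular encoders, a frozen text-embedding
# provider contract with a deterministic hashing stub, the trainable text
# projection layer, and the auxiliary classification heads used only by the
# augmented training objective.

#' Structured-data encoder configuration
#'
#' Defaults follow the tabular-deep-learning baselines used throughout:
#' 3 layers/blocks of 32 hidden units with dropout 0.1 and a 32-dimensional
#' feature output feeding the evidential layer.
#'
#' @param architecture `"mlp"`, `"resnet"`, or `"external"` (a pluggable
#'   encoder satisfying the same encode contract, e.g. an FT-Transformer-class
#'   model supplied as a function).
#' @param n_layers Number of dense layers (MLP) or residual blocks (ResNet).
#' @param hidden_units Width of hidden layers.
#' @param dropout Dropout rate in \[0, 1), applied only during training.
#' @param output_dim Feature dimension handed to the evidential layer.
#' @return An object of class `encoder_config`.
#' @export
structured_encoder_config <- function(architecture = c("mlp", "resnet", "external"),
                                      n_layers = 3L, hidden_units = 32L,
                                      dropout = 0.1, output_dim = 32L) {
  stopifnot(output_dim >= 1L, dropout >= 0, dropout < 1)
  structure(list(architecture = match.arg(architecture),
                 n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout = dropout, output_dim = as.integer(output_dim)),
            class = "encoder_config")
}

he_init <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)

#' Initialize an encoder
#'
#' Builds the trainable parameter set for the configured architecture.  For
#' `"external"`, pass the encoding function via `forward` (it is treated as
#' frozen: no parameters, no gradient).
#'
#' @param input_dim Width of the (preprocessed) input rows.
#' @param cfg A [structured_encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @param forward For `architecture = "external"`: a function mapping an
#'   N x input_dim matrix to an N x output_dim feature matrix.
#' @return An object of class `encoder`.
#' @export
init_encoder <- function(input_dim, cfg = structured_encoder_config(), seed = 1L,
                         forward = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  h <- cfg$hidden_units
  params <- list()
  if (cfg$architecture == "mlp") {
    dims <- c(input_dim, rep(h, cfg$n_layers - 1L), cfg$output_dim)
    for (i in seq_len(cfg$n_layers)) {
      params[[paste0("W", i)]] <- he_init(dims[i], dims[i + 1L])
      params[[paste0("b", i)]] <- matrix(0, 1L, dims[i + 1L])
    }
  } else if (cfg$architecture == "resnet") {
    params$W_in <- he_init(input_dim, h)
    params$b_in <- matrix(0, 1L, h)
    for (i in seq_len(cfg$n_layers)) {
      params[[paste0("Wa", i)]] <- he_init(h, h)
      params[[paste0("ba", i)]] <- matrix(0, 1L, h)
      params[[paste0("Wb", i)]] <- he_init(h, h)
      params[[paste0("bb", i)]] <- matrix(0, 1L, h)
    }
    params$W_out <- he_init(h, cfg$output_dim)
    params$b_out <- matrix(0, 1L, cfg$output_dim)
  } else {
    if (!is.function(forward))
      stop("an external encoder needs a `forward` function")
  }
  structure(list(cfg = cfg, input_dim = as.integer(input_dim),
                 params = params, forward = forward),
            class = "encoder")
}

#' Text-encoder contract
#'
#' A frozen embedding provider (no gradient flows into it) followed by one
#' trainable dense layer with 128 hidden units whose output feeds the text
#' evidential layer.  The default provider is the deterministic hashing stub;
#' a locally available pre-trained language model can plug in through the same
#' contract by supplying `provider` as a function.
#'
#' @param provider `"hashing_stub"` or a function mapping a list of token
#'   vectors to an N x provider_dim embedding matrix.
#' @param provider_dim Embedding width produced by the provider (default 256).
#' @param hidden_units Width of the trainable projection (default 128).
#' @param seed Seed for projection initialization.
#' @return An object of class `text_encoder`.
#' @export
text_encoder <- function(provider = "hashing_stub", provider_dim = 256L,
                         hidden_units = 128L, seed = 1L) {
  provider_name <- if (is.character(provider)) provider else "external"
  provider_fn <- if (is.character(provider)) {
    if (provider != "hashing_stub") stop("unknown provider: ", provider)
    function(tokens) hashing_stub(tokens, provider_dim)
  } else provider
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  structure(list(provider = provider_fn, provider_name = provider_name,
                 provider_dim = as.integer(provider_dim),
                 cfg = structured_encoder_config("mlp", n_layers = 1L,
                                                 hidden_units = hidden_units,
                                                 dropout = 0,
                                                 output_dim = hidden_units),
                 input_dim = as.integer(provider_dim),
                 params = list(W1 = he_init(provider_dim, hidden_units),
                               b1 = matrix(0, 1L, hidden_units)),
                 final_relu = TRUE),
            class = c("text_encoder", "encoder"))
}

token_hash <- function(token, dim) {
  dim <- as.integer(dim)
  h <- 0L
  for (c in utf8ToInt(token)) h <- (h * 31L + c) %% dim
  h + 1L
}

#' Deterministic hashing text embedding
#'
#' Bag-of-hashed-token counts, L2-normalized: an offline, download-free,
#' fully deterministic embedding provider used as the default text backbone.
#' Padding tokens (`"<pad>"`) and empty strings are ignored; an all-padding
#' input embeds to the zero vector.
#'
#' @param tokens A character vector of tokens (one document) or a list of such
#'   vectors.
#' @param dim Embedding dimension (number of hash buckets), default 256.
#' @return An N x dim matrix of embeddings.
#' @export
#' @examples
#' hashing_stub(c("pt", "stable"), dim = 16)
hashing_stub <- function(tokens, dim = 256L) {
  dim <- as.integer(dim)
  if (!is.list(tokens)) tokens <- list(tokens)
  all_tok <- unique(unlist(tokens, use.names = FALSE))
  all_tok <- all_tok[!is.na(all_tok) & all_tok != "" & all_tok != "<pad>"]
  buckets <- vapply(all_tok, token_hash, 1L, dim = dim)
  out <- matrix(0, length(tokens), dim)
  for (i in seq_along(tokens)) {
    tk <- tokens[[i]]
    tk <- tk[!is.na(tk) & tk != "" & tk != "<pad>"]
    if (!length(tk)) next
    cnt <- tabulate(buckets[match(tk, all_tok)], nbins = dim)
    nrm <- sqrt(sum(cnt^2))
    out[i, ] <- cnt / nrm
  }
  out
}

#' Auxiliary classification head
#'
#' A single affine map from encoder features to M class logits; used only in
#' the augmented training objective to regularize encoder representations,
#' never at inference.
#'
#' @param input_dim Encoder output dimension.
#' @param M Number of classes.
#' @param seed Seed for initialization.
#' @return An object of class `aux_head`.
#' @export
init_aux_head <- function(input_dim, M = 2L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  structure(list(params = list(W = he_init(input_dim, M), b = matrix(0, 1L, M)),
                 input_dim = as.integer(input_dim), M = as.integer(M)),
            class = "aux_head")
}

#' @rdname init_aux_head
#' @param features N x input_dim feature matrix (or a single feature vector).
#' @param head An `aux_head`.
#' @return N x M logit matrix.
#' @export
aux_logits <- function(features, head) {
  F <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  sweep(F %*% head$params$W, 2L, as.vector(head$params$b), "+")
}

# ---- differentiable encoder graphs -----------------------------------------

# Builds the encoder forward pass on an AD tape.  `pids` mirrors enc$params as
# node ids; when training, seeded inverted-dropout masks are drawn from the
# caller's RNG stream.
encoder_graph <- function(tape, enc, x_id, pids, training = FALSE) {
  cfg <- enc$cfg
  drop_node <- function(id) {
    force(id)
    if (!training || cfg$dropout <= 0) return(id)
    v <- ad_value(tape, id)
    mask <- matrix(stats::rbinom(length(v), 1L, 1 - cfg$dropout), nrow(v)) /
      (1 - cfg$dropout)
    ad_mul_const(tape, id, mask)
  }
  if (cfg$architecture == "external") {
    X <- ad_value(tape, x_id)
    return(ad_input(tape, enc$forward(X)))  # frozen: gradient stops here
  }
  if (cfg$architecture == "mlp") {
    h <- x_id
    for (i in seq_len(cfg$n_layers)) {
      h <- ad_add_bias(tape, ad_mm(tape, h, pids[[paste0("W", i)]]),
                       pids[[paste0("b", i)]])
      if (i < cfg$n_layers) h <- drop_node(ad_relu(tape, h))
    }
    if (isTRUE(enc$final_relu)) h <- ad_relu(tape, h)
    return(h)
  }
  # resnet: z + Linear(Dropout(ReLU(Linear(z)))) per block
  z <- ad_add_bias(tape, ad_mm(tape, x_id, pids$W_in), pids$b_in)
  for (i in seq_len(cfg$n_layers)) {
    u <- drop_node(ad_relu(tape, ad_add_bias(
      tape, ad_mm(tape, z, pids[[paste0("Wa", i)]]), pids[[paste0("ba", i)]])))
    z <- ad_add(tape, z, ad_add_bias(
      tape, ad_mm(tape, u, pids[[paste0("Wb", i)]]), pids[[paste0("bb", i)]]))
  }
  ad_add_bias(tape, ad_mm(tape, z, pids$W_out), pids$b_out)
}

#' Encode structured-data rows into deep features
#'
#' Deterministic evaluation-mode forward pass of a tabular encoder (dropout
#' disabled).
#'
#' @param x Preprocessed numeric row vector or N x input_dim matrix.
#' @param enc An [init_encoder()] object.
#' @return N x output_dim feature matrix.
#' @export
encode_structured <- function(x, enc) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (!is.null(enc$forward) && enc$cfg$architecture == "external")
    return(enc$forward(X))
  if (ncol(X) != enc$input_dim) stop("input width does not match encoder")
  tape <- tape_new()
  pids <- lapply(enc$params, function(p) ad_input(tape, p))
  out <- encoder_graph(tape, enc, ad_input(tape, X), pids, training = FALSE)
  ad_value(tape, out)
}

#' Encode token sequences into text features
#'
#' Applies the frozen embedding provider and the trainable 128-unit projection
#' (with ReLU).  Gradient never reaches the provider.
#'
#' @param tokens Token character vector or list of token vectors.
#' @param enc A [text_encoder()].
#' @return N x hidden_units feature matrix.
#' @export
encode_text <- function(tokens, enc) {
  E <- tryCatch(enc$provider(tokens), error = function(e)
    stop("text provider '", enc$provider_name, "' failed: ", conditionMessage(e)))
  pmax(sweep(E %*% enc$params$W1, 2L, as.vector(enc$params$b1), "+"), 0)
}
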