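#' Single-hidden-layer perceptron architecture
#'
#' The membership classifiers are multi-layer perceptrons with one hidden
#' layer of tanh units and a single tanh output unit whose sign answers
#' "is this subject in the group?". Four hidden nodes is the default — the
#' clinical tables this method targets rarely support more complexity.
#'
#' @param n_inputs Number of covariate columns (after preprocessing).
#' @param n_hidden Number of hidden units (default 4).
#' @return An object of class `mlp_architecture` with a `genome_length`
#'   field: `(n_inputs + 1) * n_hidden + (n_hidden + 1)`, biases included.
#' @export
mlp_architecture <- function(n_inputs, n_hidden = 4L) {
  if (length(n_inputs) != 1L || n_inputs < 1 || n_inputs != round(n_inputs)) {
    stop("mlp_architecture: n_inputs must be a positive integer", call. = FALSE)
  }
  if (length(n_hidden) != 1L || n_hidden < 1 || n_hidden != round(n_hidden)) {
    stop("mlp_architecture: n_hidden must be a positive integer", call. = FALSE)
  }
  n_inputs <- as.integer(n_inputs)
  n_hidden <- as.integer(n_hidden)
  structure(
    list(
      n_inputs = n_inputs,
      n_hidden = n_hidden,
      genome_length = (n_inputs + 1L) * n_hidden + (n_hidden + 1L)
    ),
    class = "mlp_architecture"
  )
}

# Split a flat genome into weight matrices. Layout: hidden weights column by
# column (n_inputs weights then the bias, per hidden unit), then the output
# weights (n_hidden) and output bias.
genome_unpack <- function(weights, arch) {
  if (length(weights) != arch$genome_length) {
    stop(sprintf("genome length %d does not match architecture (expects %d)",
                 length(weights), arch$genome_length), call. = FALSE)
  }
  nh <- arch$n_hidden
  ni <- arch$n_inputs
  hid <- matrix(weights[seq_len((ni + 1L) * nh)], nrow = ni + 1L, ncol = nh)
  out <- weights[(ni + 1L) * nh + seq_len(nh + 1L)]
  list(
    w_hidden = hid[seq_len(ni), , drop = FALSE],  # n_inputs x n_hidden
    b_hidden = hid[ni + 1L, ],
    w_out = out[seq_len(nh)],
    b_out = out[nh + 1L]
  )
}

#' Decode a genome into a membership function
#'
#' @param weights Flat numeric genome, ordered as hidden-layer weights and
#'   biases followed by output weights and bias.
#' @param arch The `mlp_architecture` the genome encodes.
#' @return A function taking a covariate matrix and returning a list with
#'   `score` (raw tanh output in (-1, 1)) and `member` (integer 0/1 mask,
#'   1 iff score > 0).
#' @export
decode_genome <- function(weights, arch) {
  stopifnot(inherits(arch, "mlp_architecture"))
  p <- genome_unpack(weights, arch)
  function(x) {
    x <- matrix(as.numeric(x), ncol = arch$n_inputs)
    h <- tanh(sweep(x %*% p$w_hidden, 2, p$b_hidden, "+"))
    score <- as.numeric(tanh(h %*% p$w_out + p$b_out))
    list(score = score, member = as.integer(score > 0))
  }
}

# Raw forward pass used in the GA hot loop: returns the logical membership
# vector directly. tanh on the output is monotone, so thresholding the
# pre-activation at 0 gives the identical decision at lower cost.
mlp_member <- function(x, params) {
  h <- tanh(x %*% params$w_hidden +
              rep(params$b_hidden, each = nrow(x)))
  drop(h %*% params$w_out) + params$b_out > 0
}

#' Classify subjects into a candidate group
#'
#' Runs the forward pass on every row of `x` and thresholds the output at
#' zero: a strictly positive output votes the subject into the group. Zero
#' maps to "not in group", the conservative choice under the minimum group
#' size constraint.
#'
#' @param weights Flat genome vector.
#' @param arch An `mlp_architecture`.
#' @param x Covariate matrix, one row per subject, `arch$n_inputs` columns.
#' @return A `group_membership` over the rows of `x`.
#' @export
classify_genome <- function(weights, arch, x) {
  stopifnot(inherits(arch, "mlp_architecture"))
  x <- as.matrix(x)
  if (ncol(x) != arch$n_inputs) {
    stop(sprintf("classify_genome: x has %d columns, architecture expects %d",
                 ncol(x), arch$n_inputs), call. = FALSE)
  }
  p <- genome_unpack(weights, arch)
  group_membership(as.integer(mlp_member(x, p)))
}

#' Write a genome to a text file
#'
#' Plain-text format: a header line `n_inputs n_hidden` followed by the flat
#' weight vector, one value per line, at full double precision.
#'
#' @param weights Flat genome vector.
#' @param arch Its `mlp_architecture`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genome <- function(weights, arch, path) {
  stopifnot(inherits(arch, "mlp_architecture"))
  if (length(weights) != arch$genome_length) {
    stop("write_genome: genome length does not match architecture", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", arch$n_inputs, arch$n_hidden), con)
  writeLines(sprintf("%.17g", weights), con)
  invisible(path)
}

#' Read a genome written by [write_genome()]
#'
#' @param path Path to the genome file.
#' @return A list with `weights` and `arch`.
#' @export
read_genome <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  arch <- mlp_architecture(hdr[1L], hdr[2L])
  weights <- as.numeric(lines[-1L])
  if (length(weights) != arch$genome_length) {
    stop("read_genome: weight count does not match the header architecture",
         call. = FALSE)
  }
  list(weights = weights, arch = arch)
}
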