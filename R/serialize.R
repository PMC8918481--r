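# Plain-text model serialization. An ensemble directory holds:
#   MANIFEST        format version, member count, classifier name
#   transform.txt   the linear map + standardization (write_transform())
#   subspaces.txt   one line of comma-separated column indices per member
#   weights.txt     the voting weights, one per line
#   member_<i>.txt  the member's effective linear decision function
# Only linear decision functions are serialized: each member is stored as
# the hyperplane (w, b, flip) with score(x) = flip * (x . w + b), which is
# exact for the default linear max-margin members. Ensembles using a custom
# base classifier must be kept in memory.

fmt17 <- function(v) paste(sprintf("%.17g", v), collapse = ",")
parse17 <- function(line) as.numeric(strsplit(line, ",")[[1L]])

linear_member_params <- function(member, score_fn, probe) {
  if (!inherits(member, "svm") || member$kernel != 0) {
    imb_stop("imbfuse_format_error",
             "only linear max-margin members can be serialized")
  }
  w <- as.numeric(crossprod(member$coefs, member$SV))
  b <- -member$rho
  raw <- as.numeric(probe %*% w + b)
  via <- score_fn(member, probe)
  flip <- if (sum(raw * via) < 0) -1 else 1
  if (max(abs(flip * raw - via)) > 1e-8 * max(1, max(abs(via)))) {
    imb_stop("imbfuse_format_error",
             "member decision function is not the stored hyperplane")
  }
  list(w = w, b = b, flip = flip)
}

#' Write a fitted ensemble to a directory of text files
#'
#' Serializes the transform, subspace indices, voting weights and every
#' member's linear decision function as delimited text (floats at 17
#' significant digits). Only ensembles whose members are the default linear
#' max-margin classifiers can be written.
#'
#' @param model An `ensemble_model` from [train_ensemble()] or
#'   [fit_pipeline()].
#' @param dir Output directory (created if missing).
#' @param probe_data Optional [labeled_dataset()] used to verify the stored
#'   hyperplanes reproduce the members' scores; a small random probe in the
#'   transformed space is generated when omitted.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(model, dir, probe_data = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_members <- length(model$members)
  writeLines(c("imbfuse-ensemble v1",
               sprintf("members:%d", n_members),
               sprintf("classifier:%s", model$classifier$name)),
             file.path(dir, "MANIFEST"))
  write_transform(model$transform, file.path(dir, "transform.txt"))
  writeLines(vapply(model$subspaces, function(s) {
    paste(s, collapse = ",")
  }, character(1L)), file.path(dir, "subspaces.txt"))
  writeLines(sprintf("%.17g", model$weights), file.path(dir, "weights.txt"))
  r <- nrow(model$transform$L)
  for (i in seq_len(n_members)) {
    m <- length(model$subspaces[[i]])
    probe <- if (is.null(probe_data)) {
      with_seed(i, matrix(stats::rnorm(5 * m), 5, m))
    } else {
      apply_transform(model$transform,
                      probe_data)$features[, model$subspaces[[i]],
                                           drop = FALSE]
    }
    p <- linear_member_params(model$members[[i]], model$classifier$score,
                              probe)
    writeLines(c(sprintf("w:%s", fmt17(p$w)),
                 sprintf("b:%s", fmt17(p$b)),
                 sprintf("flip:%d", p$flip)),
               file.path(dir, sprintf("member_%03d.txt", i)))
  }
  invisible(dir)
}

#' Read an ensemble directory written by [write_ensemble()]
#'
#' The returned model scores through the stored hyperplanes; its predictions
#' equal the original model's exactly for linear members.
#'
#' @param dir Path to the ensemble directory.
#' @return An `ensemble_model`.
#' @export
read_ensemble <- function(dir) {
  manifest <- readLines(file.path(dir, "MANIFEST"), warn = FALSE)
  if (!startsWith(manifest[1L], "imbfuse-ensemble")) {
    imb_stop("imbfuse_format_error", "not an ensemble directory")
  }
  n_members <- as.integer(sub("^members:", "", manifest[2L]))
  transform <- read_transform(file.path(dir, "transform.txt"))
  subspaces <- lapply(readLines(file.path(dir, "subspaces.txt"), warn = FALSE),
                      function(l) as.integer(strsplit(l, ",")[[1L]]))
  weights <- as.numeric(readLines(file.path(dir, "weights.txt"), warn = FALSE))
  members <- lapply(seq_len(n_members), function(i) {
    lines <- readLines(file.path(dir, sprintf("member_%03d.txt", i)),
                       warn = FALSE)
    list(w = parse17(sub("^w:", "", lines[1L])),
         b = parse17(sub("^b:", "", lines[2L])),
         flip = as.numeric(sub("^flip:", "", lines[3L])))
  })
  scorer <- base_classifier(
    fit = function(features, labels, seed = NULL) {
      imb_stop("imbfuse_format_error",
               "a deserialized ensemble cannot be refit")
    },
    score = function(member, features) {
      member$flip * as.numeric(features %*% member$w + member$b)
    },
    name = "linear_hyperplane")
  structure(list(transform = transform, subspaces = subspaces,
                 members = members, weights = weights,
                 classifier = scorer, config = NULL),
            class = "ensemble_model")
}
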