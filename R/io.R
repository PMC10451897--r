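## Manifest CSV and flat model-configuration files.

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with columns \code{path} and \code{label}
#' (0/1) and optionally \code{split}, \code{fold} and \code{seed}.
#' Paths must be unique and labels binary.
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
readManifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have 'path' and 'label' columns")
  if (anyDuplicated(m$path)) stop("manifest paths must be unique")
  if (!all(m$label %in% c(0L, 1L))) stop("manifest labels must be 0/1")
  m
}

#' @rdname readManifest
#' @param manifest data frame to write.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a flat model configuration file
#'
#' Model and head specifications as a flat \code{key: value} text file
#' (YAML scalars).  Keys: \code{f_patch, f_input, f_dim, f_depth,
#' f_heads, f_ffn} and the \code{c_*} counterparts, \code{reps},
#' \code{n_classes}, \code{eta}, \code{mil_m}, \code{mil_l}.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param milSpec a \code{\link{MILHeadSpec}}.
#' @param path file path.
#' @return \code{writeModelConfig} returns \code{path} invisibly;
#'   \code{readModelConfig} returns \code{list(spec, milSpec)}.
#' @export
writeModelConfig <- function(spec, milSpec, path) {
  b <- function(s) list(patch = s@patchSize, input = s@inputSize,
                        dim = s@embedDim, depth = s@depth,
                        heads = s@nHeads, ffn = s@ffnExpansion)
  f <- b(spec@fBranch); c_ <- b(spec@cBranch)
  cfg <- list(f_patch = f$patch, f_input = f$input, f_dim = f$dim,
              f_depth = f$depth, f_heads = f$heads, f_ffn = f$ffn,
              c_patch = c_$patch, c_input = c_$input, c_dim = c_$dim,
              c_depth = c_$depth, c_heads = c_$heads, c_ffn = c_$ffn,
              reps = spec@nReps, n_classes = spec@nClasses,
              eta = spec@eta,
              mil_m = milSpec@embedDim, mil_l = milSpec@attnDim)
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' @rdname writeModelConfig
#' @export
readModelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- ModelSpec(
    fBranch = BranchSpec(cfg$f_patch, cfg$f_input, cfg$f_dim,
                         depth = cfg$f_depth, nHeads = cfg$f_heads,
                         ffnExpansion = cfg$f_ffn),
    cBranch = BranchSpec(cfg$c_patch, cfg$c_input, cfg$c_dim,
                         depth = cfg$c_depth, nHeads = cfg$c_heads,
                         ffnExpansion = cfg$c_ffn),
    nReps = cfg$reps, nClasses = cfg$n_classes, eta = cfg$eta)
  list(spec = spec,
       milSpec = MILHeadSpec(cfg$mil_m, cfg$mil_l, cfg$n_classes))
}

#' Write per-sample predictions as JSON lines
#'
#' One JSON object per line with fields \code{path}, \code{p_normal},
#' \code{p_ealr} and \code{y_hat}.
#'
#' @param paths character vector of image paths.
#' @param predictions list of \code{\link{predictFused}} results.
#' @param path output file.
#' @export
writePredictionsJsonl <- function(paths, predictions, path) {
  lines <- vapply(seq_along(paths), function(i) {
    p <- predictions[[i]]
    jsonlite::toJSON(list(path = paths[i],
                          p_normal = p$yFused[1L],
                          p_ealr = p$yFused[2L],
                          y_hat = p$yHat),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
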