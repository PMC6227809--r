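#' Write couplings to a portable plain-text container
#'
#' A small self-describing text format: a YAML header with the dimensions,
#' convention, optional sign mask / visible set and free-form metadata,
#' followed by the thresholds and the coupling matrix in whitespace-separated
#' rows. Round-trips losslessly through \code{\link{read_couplings}} at full
#' double precision.
#'
#' @param coup A \code{\link{couplings}} object.
#' @param path Output file path.
#' @param meta Optional named list stored alongside (e.g. beta, seed,
#'   creation parameters).
#' @return \code{path}, invisibly.
#' @export
write_couplings <- function(coup, path, meta = list()) {
  validate_couplings(coup)
  N <- n_units(coup)
  header <- list(format = "dcmnet-couplings-v1", N = N,
                 convention = coup$convention,
                 visible = coup$visible, meta = meta)
  if (!is.null(coup$sign_mask)) header$sign_mask <- coup$sign_mask
  has_struct <- !is.null(coup$struct_mask)
  header$has_struct_mask <- has_struct
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("---", con)
  writeLines(yaml::as.yaml(header), con)
  writeLines("---", con)
  writeLines(paste(format_dbl(coup$theta), collapse = " "), con)
  for (i in seq_len(N))
    writeLines(paste(format_dbl(coup$J[i, ]), collapse = " "), con)
  if (has_struct)
    for (i in seq_len(N))
      writeLines(paste(coup$struct_mask[i, ], collapse = " "), con)
  invisible(path)
}

format_dbl <- function(x) formatC(x, format = "g", digits = 17)

#' Read couplings written by \code{\link{write_couplings}}
#'
#' @param path File path.
#' @return A \code{\link{couplings}} object; the stored metadata is attached
#'   as attribute \code{"meta"}.
#' @export
read_couplings <- function(path) {
  lines <- readLines(path)
  stopifnot(lines[1] == "---")
  end <- which(lines == "---")[2]
  header <- yaml::yaml.load(paste(lines[2:(end - 1)], collapse = "\n"))
  if (!identical(header$format, "dcmnet-couplings-v1"))
    stop("not a dcmnet couplings file", call. = FALSE)
  N <- header$N
  body <- lines[-seq_len(end)]
  theta <- scan(text = body[1], quiet = TRUE)
  J <- t(vapply(body[1 + seq_len(N)],
                function(l) scan(text = l, quiet = TRUE), numeric(N)))
  dimnames(J) <- NULL
  struct <- NULL
  if (isTRUE(header$has_struct_mask)) {
    struct <- t(vapply(body[1 + N + seq_len(N)],
                       function(l) scan(text = l, quiet = TRUE), numeric(N)))
    dimnames(struct) <- NULL
  }
  coup <- couplings(N, header$convention, J = J, theta = theta,
                    sign_mask = unlist(header$sign_mask),
                    struct_mask = struct,
                    visible = unlist(header$visible))
  attr(coup, "meta") <- header$meta
  coup
}

#' Write a pattern set as plain text
#'
#' One pattern per line, encoded as \code{+}/\code{-} characters (\code{-1/+1}
#' coding) or \code{1}/\code{0} characters, preceded by a YAML header with
#' the generation metadata.
#'
#' @param patterns A \code{\link{pattern_set}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  meta <- patterns$meta
  meta$dictionary <- NULL              # regenerate rather than store
  header <- list(format = "dcmnet-patterns-v1",
                 M = nrow(patterns$xi), N = ncol(patterns$xi),
                 convention = patterns$convention, meta = meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("---", con)
  writeLines(yaml::as.yaml(header), con)
  writeLines("---", con)
  chars <- if (patterns$convention == "pm1")
    ifelse(patterns$xi > 0, "+", "-") else ifelse(patterns$xi > 0, "1", "0")
  writeLines(apply(chars, 1, paste, collapse = ""), con)
  invisible(path)
}

#' Read a pattern set written by \code{\link{write_patterns}}
#'
#' @param path File path.
#' @return A \code{\link{pattern_set}}.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "---")[2]
  header <- yaml::yaml.load(paste(lines[2:(end - 1)], collapse = "\n"))
  if (!identical(header$format, "dcmnet-patterns-v1"))
    stop("not a dcmnet patterns file", call. = FALSE)
  body <- lines[-seq_len(end)]
  rows <- lapply(strsplit(body, ""), function(ch)
    if (header$convention == "pm1") ifelse(ch == "+", 1, -1)
    else as.numeric(ch))
  pattern_set(do.call(rbind, rows), header$convention,
              meta = if (is.null(header$meta)) list() else header$meta)
}

#' Derive independent sub-seeds from one experiment seed
#'
#' All stochastic components of an experiment draw their seeds from a single
#' master seed through this helper: the master seed seeds R's generator once
#' and \code{n} sub-seeds are drawn uniformly from the 31-bit integer range.
#'
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds.
#' @return Integer vector of length \code{n}.
#' @export
split_seed <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

required_config_keys <- function(experiment) {
  base <- c("experiment", "seed", "network")
  extra <- switch(experiment,
    capacity  = c("rule", "criterion"),
    palimpsest = c("n_stream"),
    spurious  = c("rule", "n_patterns", "n_walks", "walk_len"),
    train     = c("patterns_file", "out_couplings"),
    baseline  = c("rule", "n_patterns", "criterion"),
    stop("unknown experiment kind: ", experiment, call. = FALSE))
  c(base, extra)
}

#' Validate an experiment configuration
#'
#' @param config Named list, typically from \code{yaml::read_yaml}.
#' @return The config, invisibly; otherwise an error naming every missing or
#'   invalid key.
#' @export
validate_config <- function(config) {
  if (is.null(config$experiment))
    stop("config error: missing key `experiment`", call. = FALSE)
  need <- required_config_keys(config$experiment)
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config error: missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(config$network$N))
    stop("config error: missing key `network.N`", call. = FALSE)
  invisible(config)
}

config_params <- function(config) {
  net <- config$network
  dynamics_params(beta = if (is.null(net$beta)) 3 else net$beta,
                  deterministic = isTRUE(net$deterministic))
}

config_criterion <- function(config) {
  cr <- config$criterion
  if (is.null(cr)) return(retrieval_criterion())
  do.call(retrieval_criterion, cr)
}

config_protocol <- function(config, default = field_protocol()) {
  if (is.null(config$protocol)) return(default)
  do.call(field_protocol, config$protocol)
}

config_generator <- function(config) {
  pg <- config$patterns
  if (is.null(pg) || is.null(pg$kind) || pg$kind == "iid")
    return(function(N, M) iid_patterns(N, M))
  switch(pg$kind,
    biased = function(N, M) biased_patterns(N, M, b = pg$b),
    sparse = function(N, M) sparse_patterns(N, M, f = pg$f),
    dictionary = function(N, M)
      dictionary_patterns(N, M, L = pg$L, F = pg$F, f = pg$f),
    stop("unknown pattern generator: ", pg$kind, call. = FALSE))
}

#' Run a configured experiment
#'
#' Dispatches on \code{config$experiment} (\code{"capacity"},
#' \code{"palimpsest"}, \code{"spurious"}, \code{"train"},
#' \code{"baseline"}), executes it with all randomness derived from
#' \code{config$seed}, and writes into \code{outdir}: a tidy
#' \code{results.csv}, a \code{manifest.yaml} (full config, seed, package and
#' R version) sufficient to reproduce the run bit-identically, and for
#' training runs the learned couplings.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param outdir Output directory, created if needed.
#' @return The results data frame, invisibly.
#' @export
run_experiment <- function(config, outdir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  params <- config_params(config)
  N <- config$network$N
  res <- switch(config$experiment,
    capacity = {
      ms <- max_storage_load(config$rule, N, config_criterion(config), params,
                             generator = config_generator(config),
                             protocol = config_protocol(config),
                             n_reps = if (is.null(config$n_reps)) 3
                                      else config$n_reps)
      data.frame(experiment = "capacity", rule = config$rule, N = N,
                 rep = seq_along(ms$per_rep), alpha_max = ms$per_rep,
                 seed = config$seed)
    },
    palimpsest = {
      pc <- palimpsest_capacity(N, config$n_stream, params = params,
                                criterion = config_criterion(config))
      data.frame(experiment = "palimpsest", N = N,
                 presented = pc$tail_counts$presented,
                 retrievable = pc$tail_counts$retrievable,
                 one_step_stable = pc$tail_counts$one_step_stable,
                 seed = config$seed)
    },
    spurious = {
      pats <- config_generator(config)(N, config$n_patterns)
      coup <- build_rule(config$rule, config_protocol(config),
                         learning_params(eta = 1 / N), params,
                         config_criterion(config), 30, NULL)(pats)
      cen <- spurious_census(coup, pats, config$n_walks, config$walk_len,
                             params)
      data.frame(experiment = "spurious", rule = config$rule, N = N,
                 n_patterns = config$n_patterns,
                 n_spurious = cen$n_spurious, n_matched = cen$n_matched,
                 seed = config$seed)
    },
    train = {
      pats <- read_patterns(config$patterns_file)
      coup <- couplings(N, pats$convention)
      fit <- train_cyclic(coup, pats, config_protocol(config),
                          learning_params(eta = 1 / N), params,
                          config_criterion(config))
      write_couplings(fit$couplings, file.path(outdir, config$out_couplings),
                      meta = list(seed = config$seed, beta = params$beta))
      data.frame(experiment = "train", N = N,
                 pattern = seq_along(fit$stored), stored = fit$stored,
                 cycles_used = fit$cycles_used, seed = config$seed)
    },
    baseline = {
      pats <- config_generator(config)(N, config$n_patterns)
      coup <- build_rule(config$rule, field_protocol(),
                         learning_params(eta = 1 / N), params,
                         config_criterion(config), 30, NULL)(pats)
      stored <- retrieval_test(coup, pats, config_criterion(config), params)
      data.frame(experiment = "baseline", rule = config$rule, N = N,
                 pattern = seq_along(stored), stored = stored,
                 seed = config$seed)
    })
  utils::write.csv(res, file.path(outdir, "results.csv"), row.names = FALSE)
  manifest <- list(config = config,
                   package = as.character(utils::packageVersion("dcmnet")),
                   r_version = R.version.string)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(res)
}
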