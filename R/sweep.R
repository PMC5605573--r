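#' Parameter sweep over selection, dominance and mutation
#'
#' Evaluates exact allele-age moments (and optionally the absorption summary)
#' over the grid `two_Ne_s x h x theta` at fixed `Ne` and observed count `x`.
#' Selection is specified population-scaled (`2*Ne*s`, the scale on which the
#' age-imbalance and stochastic-slowdown effects are naturally expressed) and
#' converted internally to `s`. Within each grid point one transition matrix
#' is built and one LU factorization is shared across every requested
#' quantity. Per-point failures are captured in the `error` column and the
#' sweep continues; row order follows `expand.grid(two_Ne_s, h, theta)` and
#' is deterministic.
#'
#' @param Ne effective diploid population size.
#' @param two_Ne_s numeric vector of population-scaled selection coefficients.
#' @param h numeric vector of dominance coefficients.
#' @param theta numeric vector of population-scaled mutation rates (`>= 0`;
#'   0 means no mutation).
#' @param x observed copy count.
#' @param p founding copy count, or `"prior"` to integrate over a
#'   [starting_copy_prior()] with threshold `epsilon` (per-theta).
#' @param epsilon prior inclusion threshold when `p = "prior"`.
#' @param cutoff sparsity cutoff for the transition matrix.
#' @param absorption also compute absorption probabilities and conditional
#'   times (start state: `absorption_start`).
#' @param absorption_start `"x"` (default) or `"p"`: state from which
#'   absorption times are measured.
#' @return data.frame, one row per grid point, columns `Ne`, `two_Ne_s`, `s`,
#'   `h`, `theta`, `u`, `v`, `x`, `p`, `mean`, `variance`, `sd`,
#'   `normalizer`, optionally `prob_extinction`, `prob_fixation`,
#'   `time_unconditional`, `time_given_extinction`, `time_given_fixation`,
#'   and `error`.
#' @examples
#' age_sweep(200, two_Ne_s = c(-1, 0, 1), h = 0.5, theta = 0.1)
#' @export
age_sweep <- function(Ne, two_Ne_s = 0, h = 0.5, theta = 0, x = 10, p = 1,
                      epsilon = 1e-5, cutoff = 1e-12,
                      absorption = FALSE, absorption_start = c("x", "p")) {
  absorption_start <- match.arg(absorption_start)
  grid <- expand.grid(two_Ne_s = two_Ne_s, h = h, theta = theta,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) stop("empty parameter grid")
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    tns <- grid$two_Ne_s[g]; hh <- grid$h[g]; th <- grid$theta[g]
    out <- data.frame(Ne = Ne, two_Ne_s = tns, s = tns / (2 * Ne), h = hh,
                      theta = th, u = th / (4 * Ne), v = th / (4 * Ne),
                      x = x, p = NA_character_,
                      mean = NA_real_, variance = NA_real_, sd = NA_real_,
                      normalizer = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    if (absorption)
      out[c("prob_extinction", "prob_fixation", "time_unconditional",
            "time_given_extinction", "time_given_fixation")] <- NA_real_
    res <- tryCatch({
      model <- wf_model(Ne, s = tns / (2 * Ne), h = hh, theta = th)
      ts <- transient_system(wf_transition_matrix(model, cutoff = cutoff))
      f <- transient_factorization(ts)
      start <- if (identical(p, "prior")) {
        if (th <= 0) stop("the founding-copy prior requires theta > 0")
        starting_copy_prior(th, epsilon)
      } else p
      am <- allele_age_moments(ts, x = x, p = start, f = f)
      out$p <- if (identical(p, "prior")) "prior" else as.character(p)
      out$mean <- am$mean; out$variance <- am$variance; out$sd <- am$sd
      out$normalizer <- am$normalizer
      if (absorption) {
        st <- if (absorption_start == "x") x else
          if (identical(p, "prior")) start else p
        ab <- absorption_summary(ts, st, f)
        out$prob_extinction <- ab$prob_extinction
        out$prob_fixation <- ab$prob_fixation
        out$time_unconditional <- ab$time_unconditional
        out$time_given_extinction <- ab$time_given_extinction
        out$time_given_fixation <- ab$time_given_fixation
      }
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
    rows[[g]] <- res
  }
  do.call(rbind, rows)
}

#' Write sweep results as TSV and JSON with provenance
#'
#' Serializes a results table to a tab-separated file and a JSON report. The
#' JSON carries a provenance block (package version, cutoff/seed if given,
#' timestamp) alongside the verbatim results, and `read_report()` restores a
#' table identical to the one written (the timestamp lives only in the
#' provenance block). Numbers in the TSV are written with 6 significant
#' digits by default; the JSON keeps full precision.
#'
#' @param results data.frame, e.g. from [age_sweep()].
#' @param tsv,json output paths (either may be `NULL` to skip).
#' @param provenance named list merged into the provenance block.
#' @param digits significant digits for the TSV.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, tsv = NULL, json = NULL,
                         provenance = list(), digits = 6) {
  paths <- character(0)
  if (!is.null(tsv)) {
    fmt <- results
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], signif, digits = digits)
    utils::write.table(fmt, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tsv)
  }
  if (!is.null(json)) {
    payload <- list(
      provenance = c(list(package = "wfage",
                          version = as.character(utils::packageVersion("wfage")),
                          timestamp = format(Sys.time(), tz = "UTC")),
                     provenance),
      results = results)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, json)
  }
  invisible(paths)
}

#' @rdname write_report
#' @param path a JSON file written by `write_report()`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- as.data.frame(payload$results, stringsAsFactors = FALSE)
  attr(res, "provenance") <- payload$provenance
  res
}

#' Read model parameters from a JSON config file
#'
#' Accepts keys `Ne`, `s`, `h`, `u`, `v`, `theta`, `cutoff` (any subset;
#' `theta` wins over `u`/`v`). Mirrors the command-line flags of the bundled
#' CLI script.
#'
#' @param path JSON file.
#' @return list with `model` (a [wf_model()]) and `cutoff`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg), c("Ne", "s", "h", "u", "v", "theta"))]
  model <- do.call(wf_model, args)
  list(model = model,
       cutoff = if (!is.null(cfg$cutoff)) cfg$cutoff else 1e-12)
}
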