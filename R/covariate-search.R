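#' Two-step (forward inclusion / backward elimination) covariate search
#'
#' Stepwise covariate model building on top of the allometrically scaled base
#' model. The forward pass repeatedly adds, one at a time, the candidate whose
#' inclusion drops the OFV the most, provided the drop exceeds
#' `forward_dofv` (default 3.84, the chi-square 1-df 5% point). The backward
#' pass then removes each included effect unless its removal raises the OFV
#' by more than `backward_dofv` (default 6.63, the 1% point). Candidates whose
#' fits fail to converge are skipped and logged in the trace; the search
#' continues.
#'
#' Allometric weight scaling is part of the base model and is never searched.
#'
#' @param dataset A `clz_dataset`.
#' @param base A converged `clz_fit` of the base (no-covariate) model, from
#'   [pk_fit()] with `effects = list()`.
#' @param candidates List of candidate [covariate_effect()]s (initial `q`
#'   values are the search starting points).
#' @param forward_dofv,backward_dofv Inclusion/retention OFV thresholds.
#' @return A `clz_covsearch` list: `selected` (effects with fitted
#'   coefficients), `trace` (tibble of every tested move and its dOFV),
#'   `base_ofv`, `final_ofv`, `final_fit`.
#' @examples
#' \donttest{
#' ds <- simulate_cohort(pop_params(), design_spec(n_subjects = 50, p_zop = 0.25,
#'   seed = 3))
#' base <- pk_fit(ds, se = FALSE)
#' covariate_search(ds, base, candidates = zop_effect(0))
#' }
#' @export
covariate_search <- function(dataset, base, candidates,
                             forward_dofv = 3.84, backward_dofv = 6.63) {
  stopifnot(inherits(base, "clz_fit"))
  if (!base$converged) stop("base fit did not converge", call. = FALSE)
  dataset <- as_pk_dataset(dataset)

  trace <- list()
  note <- function(phase, step, name, ofv_ref, ofv_new, action) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      phase = phase, step = step, candidate = name,
      ofv = ofv_new, dofv = ofv_ref - ofv_new, action = action
    )
  }
  eff_label <- function(e) paste0(e$name, "~", e$target)

  refit <- function(effs, init_pop) {
    out <- tryCatch(
      pk_fit(dataset, init = init_pop, effects = effs, se = FALSE),
      error = function(e) NULL
    )
    if (!is.null(out) && !out$converged) out <- NULL
    out
  }

  selected <- list()
  current <- base
  remaining <- candidates
  step <- 0L

  repeat { # forward inclusion
    step <- step + 1L
    best <- NULL
    best_i <- NA_integer_
    for (i in seq_along(remaining)) {
      cand <- remaining[[i]]
      f <- refit(c(selected, list(cand)), current$pop)
      if (is.null(f)) {
        note("forward", step, eff_label(cand), current$ofv, NA_real_,
             "skipped (non-convergent)")
        next
      }
      note("forward", step, eff_label(cand), current$ofv, f$ofv, "tested")
      if (is.null(best) || f$ofv < best$ofv) {
        best <- f
        best_i <- i
      }
    }
    if (is.null(best) || current$ofv - best$ofv <= forward_dofv) break
    selected <- c(selected, remaining[best_i])
    note("forward", step, eff_label(remaining[[best_i]]), current$ofv,
         best$ofv, "included")
    remaining <- remaining[-best_i]
    current <- best
    if (!length(remaining)) break
  }

  repeat { # backward elimination
    if (!length(selected)) break
    dropped <- FALSE
    for (i in seq_along(selected)) {
      step <- step + 1L
      f <- refit(selected[-i], current$pop)
      if (is.null(f)) {
        note("backward", step, eff_label(selected[[i]]), current$ofv,
             NA_real_, "skipped (non-convergent)")
        next
      }
      rise <- f$ofv - current$ofv
      if (rise <= backward_dofv) {
        note("backward", step, eff_label(selected[[i]]), current$ofv, f$ofv,
             "removed")
        selected <- selected[-i]
        current <- f
        dropped <- TRUE
        break
      }
      note("backward", step, eff_label(selected[[i]]), current$ofv, f$ofv,
           "retained")
    }
    if (!dropped) break
  }

  structure(
    list(
      selected = current$effects,
      trace = if (length(trace)) dplyr::bind_rows(trace) else
        tibble::tibble(phase = character(), step = integer(),
                       candidate = character(), ofv = double(),
                       dofv = double(), action = character()),
      base_ofv = base$ofv, final_ofv = current$ofv, final_fit = current
    ),
    class = "clz_covsearch"
  )
}

#' @export
print.clz_covsearch <- function(x, ...) {
  cat("<clz_covsearch> stepwise covariate search\n")
  cat(sprintf("  base OFV %.3f -> final OFV %.3f\n", x$base_ofv, x$final_ofv))
  if (length(x$selected)) {
    for (e in x$selected) {
      cat(sprintf("  selected: %s on %s (%s, q = %.4g)\n",
                  e$name, e$target, e$kind, e$q))
    }
  } else {
    cat("  no covariate selected\n")
  }
  invisible(x)
}
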