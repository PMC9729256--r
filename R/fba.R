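#' Medium specification
#'
#' Describes the in-silico growth medium: per-exchange maximum uptake rates,
#' an optional cap on total carbon uptake, and the set of always-open
#' inorganic exchanges (water, protons, oxygen, phosphate, sulfate, ammonium
#' and similar). Any exchange reaction not named in `uptake` or `always_open`
#' is closed for uptake (lower bound 0); secretion is never restricted by the
#' medium. Uptake follows the standard sign convention: negative exchange
#' flux is uptake, positive is secretion.
#'
#' The carbon cap bounds total carbon *consumption*,
#' `sum_e carbon(metabolite_e) * uptake_e <= carbon_cap` in
#' c-mmol gCDW^-1 h^-1, counting only the uptake direction of each exchange
#' (implemented with nonnegative uptake-split variables, so secretion never
#' relaxes the cap).
#'
#' @param uptake named numeric vector: exchange reaction id -> maximum uptake
#'   rate (mmol gCDW^-1 h^-1); use `Inf` for unbounded.
#' @param carbon_cap optional positive total-carbon-uptake cap
#'   (c-mmol gCDW^-1 h^-1).
#' @param always_open character vector of exchange reaction ids left fully
#'   open for uptake.
#' @return object of class `medium_spec`.
#' @export
medium_spec <- function(uptake = numeric(), carbon_cap = NULL,
                        always_open = character()) {
  if (length(uptake) && (is.null(names(uptake)) || any(!nzchar(names(uptake))))) {
    stop("uptake must be a named vector of exchange reaction ids", call. = FALSE)
  }
  if (any(uptake < 0)) stop("uptake limits must be >= 0", call. = FALSE)
  if (!is.null(carbon_cap) && carbon_cap <= 0) {
    stop("carbon_cap must be > 0 when set", call. = FALSE)
  }
  structure(list(uptake = uptake, carbon_cap = carbon_cap,
                 always_open = always_open),
            class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("<medium_spec>\n")
  if (length(x$uptake)) {
    for (i in seq_along(x$uptake)) {
      cat("  ", names(x$uptake)[i], ": uptake <= ", x$uptake[[i]], "\n", sep = "")
    }
  }
  if (length(x$always_open)) {
    cat("  always open: ", paste(x$always_open, collapse = ", "), "\n", sep = "")
  }
  cat("  carbon cap: ",
      if (is.null(x$carbon_cap)) "none" else x$carbon_cap, "\n", sep = "")
  invisible(x)
}

# Assemble the FBA constraint system for a model + medium.
# Variables: [v (reactions); u (uptake splits for carbon-bearing exchanges)].
# Rows: S v = 0; per split u_e + v_e >= 0; carbon cap row sum c_e u_e <= cap.
fba_system <- function(model, medium) {
  stopifnot(inherits(model, "gem"), inherits(medium, "medium_spec"))
  rx <- model$reactions
  n <- nrow(rx)
  lb <- rx$lower_bound
  ub <- rx$upper_bound

  ex <- which(rx$is_exchange)
  bad <- setdiff(names(medium$uptake), rx$id)
  if (length(bad)) {
    stop("medium names exchange reaction(s) not in the model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (i in ex) {
    id <- rx$id[[i]]
    if (id %in% names(medium$uptake)) {
      lb[i] <- max(lb[i], -medium$uptake[[id]])
    } else if (id %in% medium$always_open) {
      # keep the model's lower bound (fully open)
    } else {
      lb[i] <- max(lb[i], 0)  # closed for uptake
    }
  }
  S <- gem_smatrix(model)
  A <- S
  rhs <- rep(0, nrow(S))
  sense <- rep("=", nrow(S))
  var_ids <- rx$id

  if (!is.null(medium$carbon_cap)) {
    forms <- stats::setNames(model$metabolites$formula, model$metabolites$id)
    carbon_ex <- integer()
    carbons <- numeric()
    for (i in ex) {
      if (lb[i] >= 0) next                      # no uptake possible
      met <- names(rx$stoich[[i]])
      f <- forms[[met]]
      nc <- if (is.na(f)) 0L else carbon_count(f)
      if (nc > 0L) { carbon_ex <- c(carbon_ex, i); carbons <- c(carbons, nc) }
    }
    k <- length(carbon_ex)
    if (k) {
      A <- cbind(A, matrix(0, nrow(A), k))
      # u_e >= -v_e  <=>  v_e + u_e >= 0
      cpl <- matrix(0, k, ncol(A))
      for (j in seq_len(k)) {
        cpl[j, carbon_ex[[j]]] <- 1
        cpl[j, n + j] <- 1
      }
      cap_row <- c(rep(0, n), carbons)
      A <- rbind(A, cpl, cap_row)
      rhs <- c(rhs, rep(0, k), medium$carbon_cap)
      sense <- c(sense, rep(">=", k), "<=")
      lb <- c(lb, rep(0, k))
      ub <- c(ub, rep(Inf, k))
      var_ids <- c(var_ids, paste0(".uptake_", rx$id[carbon_ex]))
    }
  }
  list(A = A, rhs = rhs, sense = sense, lb = lb, ub = ub,
       n_reactions = n, var_ids = var_ids)
}

new_flux_solution <- function(status, model, v = NULL, method = "fba") {
  fluxes <- if (is.null(v)) stats::setNames(rep(NA_real_, nrow(model$reactions)),
                                            model$reactions$id)
            else stats::setNames(v, model$reactions$id)
  obj <- if (is.null(v) || is.na(model$objective)) NA_real_
         else unname(fluxes[[model$objective]])
  structure(list(status = status, objective = obj, fluxes = fluxes,
                 total_flux = if (is.null(v)) NA_real_ else sum(abs(v)),
                 method = method, model_id = model$id),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> [", x$method, "] ", x$model_id, "\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  cat("  objective: ", format(x$objective, digits = 6), " h^-1\n", sep = "")
  cat("  |v|_1:     ", format(x$total_flux, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the biomass (objective) flux subject to steady state
#' (`S v = 0`), reaction bounds, the medium's uptake limits, and -- when the
#' medium sets one -- the total-carbon-uptake cap. Infeasibility or
#' unboundedness is reported in `status`, never as silent zeros.
#'
#' @param model a [gem] with an objective reaction.
#' @param medium a [medium_spec].
#' @param block optional character vector of reaction ids to constrain to
#'   zero flux (e.g. an enzyme whose presence lacks genomic support).
#' @return a `flux_solution`: `status`, `objective` (specific growth rate,
#'   h^-1), `fluxes` (named vector), `total_flux`.
#' @export
solve_fba <- function(model, medium = medium_spec(), block = character()) {
  if (is.na(model$objective)) {
    stop("model '", model$id, "' has no objective reaction", call. = FALSE)
  }
  sys <- fba_system(model, medium)
  if (length(block)) {
    idx <- match(block, model$reactions$id)
    if (anyNA(idx)) stop("unknown reaction(s) in block: ",
                         paste(block[is.na(idx)], collapse = ", "), call. = FALSE)
    sys$lb[idx] <- 0; sys$ub[idx] <- 0
  }
  obj <- numeric(ncol(sys$A))
  obj[match(model$objective, model$reactions$id)] <- 1
  res <- lp_solve(obj, sys$A, sys$rhs, sys$sense, sys$lb, sys$ub,
                  maximize = TRUE)
  if (res$status != "optimal") return(new_flux_solution(res$status, model))
  v <- res$x[seq_len(sys$n_reactions)]
  sol <- new_flux_solution("optimal", model, v, method = "fba")
  check_steady_state(model, v)
  sol
}

check_steady_state <- function(model, v, tol = 1e-7) {
  resid <- max(abs(gem_smatrix(model) %*% v))
  if (length(resid) && resid > tol) {
    warning("steady-state residual ", format(resid), " exceeds ", tol,
            call. = FALSE)
  }
  invisible(resid)
}

#' Parsimonious flux balance analysis
#'
#' Two-stage optimization: first [solve_fba()] finds the optimal biomass
#' flux; then total absolute flux `sum |v|` is minimized while biomass is
#' held at that optimum (within relative tolerance `biomass_tol`). The
#' absolute values are linearized by the standard flux split
#' `v = v+ - v-`, `v+, v- >= 0`. Parsimonious solutions suppress futile
#' cycles that plain FBA leaves undetermined.
#'
#' @inheritParams solve_fba
#' @param biomass_tol relative slack below the fixed biomass optimum; kept
#'   tiny (1e-9) so the parsimonious solution's biomass is numerically
#'   indistinguishable from the FBA optimum while guarding against
#'   round-off infeasibility.
#' @return a `flux_solution` with `total_flux` the minimized `sum |v|`.
#' @export
solve_pfba <- function(model, medium = medium_spec(), block = character(),
                       biomass_tol = 1e-9) {
  fba <- solve_fba(model, medium, block)
  if (fba$status != "optimal") return(fba)
  opt <- fba$objective

  sys <- fba_system(model, medium)
  if (length(block)) {
    idx <- match(block, model$reactions$id)
    sys$lb[idx] <- 0; sys$ub[idx] <- 0
  }
  n <- sys$n_reactions
  n_aux <- ncol(sys$A) - n
  bi <- match(model$objective, model$reactions$id)

  # pin biomass at its optimum (within tolerance)
  lb <- sys$lb; ub <- sys$ub
  lb[bi] <- max(lb[bi], opt * (1 - biomass_tol) - 1e-12)

  # v_i = vp_i - vn_i; vp in [max(lb,0), max(ub,0)], vn in [max(-ub,0), max(-lb,0)]
  lb_v <- lb[seq_len(n)]; ub_v <- ub[seq_len(n)]
  A0 <- sys$A[, seq_len(n), drop = FALSE]
  Aaux <- sys$A[, -seq_len(n), drop = FALSE]
  A2 <- cbind(A0, -A0, Aaux)
  lb2 <- c(pmax(lb_v, 0), pmax(-ub_v, 0), lb[-seq_len(n)])
  ub2 <- c(pmax(ub_v, 0), pmax(-lb_v, 0), ub[-seq_len(n)])
  obj2 <- c(rep(1, 2L * n), rep(0, n_aux))
  res <- lp_solve(obj2, A2, sys$rhs, sys$sense, lb2, ub2, maximize = FALSE)
  if (res$status != "optimal") return(new_flux_solution(res$status, model))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  sol <- new_flux_solution("optimal", model, v, method = "pfba")
  sol$total_flux <- sum(abs(v))
  check_steady_state(model, v)
  sol
}

#' Binary growth test
#'
#' `TRUE` iff FBA is optimal and the biomass flux exceeds `threshold`. The
#' default threshold (1e-6 h^-1) is the conventional numerically-safe cutoff
#' separating growth from solver noise.
#'
#' @inheritParams solve_fba
#' @param threshold growth-rate cutoff (h^-1).
#' @return logical scalar.
#' @export
growth_test <- function(model, medium = medium_spec(), threshold = 1e-6,
                        block = character()) {
  if (is.na(model$objective)) return(FALSE)
  sol <- solve_fba(model, medium, block)
  sol$status == "optimal" && sol$objective > threshold
}

#' Export a flux solution as TSV
#'
#' @param solution a `flux_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fluxes_tsv <- function(solution, path) {
  df <- data.frame(reaction_id = names(solution$fluxes),
                   flux = unname(solution$fluxes), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
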