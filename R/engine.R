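#' Enzyme-synthesis induction multiplier
#'
#' The concentration-response model reused dynamically: the relative
#' synthesis rate of an induced enzyme at unbound inducer concentration
#' `cu` is `1 + (indmax - 1) * cu / (indc50 + cu)`, and the relative
#' enzyme amount follows `d(E/E0)/dt = kdeg * (multiplier - E/E0)`.
#'
#' @param cu Unbound inducer concentration (umol/L), >= 0.
#' @param indmax Maximal fold induction (calibrated; >= 1).
#' @param indc50 Half-maximal concentration (umol/L).
#' @return Dimensionless synthesis multiplier in [1, indmax].
#' @export
induction_multiplier <- function(cu, indmax, indc50) {
  if (any(cu < 0)) stop("unbound concentration must be >= 0")
  1 + (indmax - 1) * cu / (indc50 + cu)
}

#' Competitive inhibition of an activity
#'
#' Scales a baseline activity by `1 / (1 + cu / ki)`.
#'
#' @param base_activity Uninhibited activity (any units).
#' @param cu Unbound inhibitor concentration (umol/L).
#' @param ki Competitive inhibition constant (umol/L), > 0.
#' @return The inhibited activity.
#' @export
inhibited_activity <- function(base_activity, cu, ki) {
  if (any(ki <= 0)) stop("ki must be > 0")
  base_activity / (1 + cu / ki)
}

# ---- internal: precompute per-compound rate constants -----------------------

build_engine_pars <- function(spec) {
  sys <- spec$system
  scale_mg <- sys$liver_mass * sys$mppgl          # mg microsomal protein
  lapply(spec$compounds, function(cm) {
    ab <- sys$enzyme_abundance
    miss <- setdiff(names(cm$clint_enzyme), names(ab))
    if (length(miss))
      stop("no abundance for enzyme(s): ", paste(miss, collapse = ", "))
    # unbound hepatic CL_int per enzyme, L/h
    clint_u <- cm$clint_enzyme * ab[names(cm$clint_enzyme)] *
      scale_mg * 60 / 1e6
    frac_m2 <- cm$frac_to_m2[names(cm$clint_enzyme)]
    if (cm$clint_hlm_additional > 0) {
      clint_u <- c(clint_u, hlm = cm$clint_hlm_additional * scale_mg * 60 / 1e6)
      frac_m2 <- c(frac_m2, hlm = 0)
    }
    is_3a4 <- names(clint_u) == "CYP3A4"
    cl3a4_gut <- if ("CYP3A4" %in% names(cm$clint_enzyme))
      cm$clint_enzyme[["CYP3A4"]] * sys$gut_cyp3a4_amount * 60 / 1e6 else 0
    vc <- cm$vss * sys$body_weight * cm$vc_frac
    list(name = cm$name, mw = cm$mw, fu = cm$fu, fu_gut = cm$fu_gut,
         bp = cm$bp, vc = vc, vp = cm$vss * sys$body_weight - vc,
         ka = cm$ka, kloss = if (cm$fa < 1) cm$ka * (1 - cm$fa) / cm$fa else 0,
         cl_d = cm$cl_d, cl_r = cm$cl_r, frac_clr_oat3 = cm$frac_clr_oat3,
         fub = cm$fu / cm$bp,
         clint_u = clint_u, frac_m2 = frac_m2, is_3a4 = is_3a4,
         has_3a4 = any(is_3a4), any_m2 = any(frac_m2 > 0),
         cl3a4_gut = cl3a4_gut,
         cl_pgp_gut = cm$clint_pgp_in_vitro * cm$raf_ref * 60 / 1000, # L/h
         ki_cyp3a = cm$ki_cyp3a, ki_pgp = cm$ki_pgp, ki_oat3 = cm$ki_oat3,
         indmax = cm$indmax_calibrated, indc50 = cm$indc50)
  })
}

state_names <- function(compounds) {
  per <- c("gut", "ent", "cen", "per", "cum_unabs", "cum_gutmet",
           "cum_hepmet", "cum_ren", "cum_formed")
  c(as.vector(t(outer(compounds, per, paste, sep = "."))),
    "E_liver_CYP3A4", "E_gut_CYP3A4")
}

#' Simulate the perpetrator-victim PBPK system
#'
#' Integrates, per compound, a gut-lumen depot, a well-mixed enterocyte
#' compartment (site of gut CYP3A metabolism and of P-gp secretion back to
#' the lumen), and a central + peripheral distribution model with hepatic
#' elimination by the well-stirred model and first-order renal clearance.
#' Hepatic first-pass extraction is applied to the portal inflow. Liver
#' and gut CYP3A4 pools turn over with `d(E/E0)/dt = kdeg * (mult - E/E0)`
#' driven by the perpetrators' unbound hepatic-inlet and enterocyte
#' concentrations respectively; competitive inhibition scales CYP3A
#' intrinsic clearance, P-gp secretion and (optionally) OAT3-mediated
#' renal clearance. Parent-to-metabolite hepatic flux is routed
#' mole-per-mole into the metabolite's central compartment according to
#' the parent's per-enzyme formation fractions.
#'
#' @param spec A [model_spec()].
#' @param regimens A [regimen()] or list of regimens.
#' @param duration Simulation end time (h).
#' @param solver_opts List of solver options: `dt` output step (h, default
#'   0.1), `atol` (default 1e-10), `rtol` (default 1e-8), `clamp` (named
#'   vector holding a compound's concentration constant in every
#'   compartment, for verification runs), `method` (default `"lsoda"`).
#' @return An object of class `sim_result`: list with `time`, the full
#'   state matrix `states` (amounts in umol; enzyme pools relative to
#'   baseline), `spec`, `regimens`, `doses_umol`.
#' @export
simulate_pbpk <- function(spec, regimens, duration, solver_opts = list()) {
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  stopifnot(inherits(spec, "model_spec"))
  opts <- utils::modifyList(
    list(dt = 0.1, atol = 1e-10, rtol = 1e-8, clamp = NULL,
         method = "lsoda"), solver_opts)
  pars <- build_engine_pars(spec)
  cn <- names(spec$compounds)
  for (r in regimens) {
    if (!r$compound %in% cn) stop("regimen for unknown compound ", r$compound)
    if (r$start + (r$n_doses - 1) * r$interval > duration)
      stop("duration does not cover all doses")
  }
  sn <- state_names(cn)
  y0 <- stats::setNames(rep(0, length(sn)), sn)
  y0[c("E_liver_CYP3A4", "E_gut_CYP3A4")] <- 1
  sys <- spec$system
  clamp <- opts$clamp
  if (!is.null(clamp)) {
    for (nm in names(clamp)) {
      p <- pars[[nm]]
      y0[paste0(nm, ".cen")] <- clamp[[nm]] * p$vc
      y0[paste0(nm, ".per")] <- clamp[[nm]] * p$vp
      y0[paste0(nm, ".ent")] <- clamp[[nm]] * sys$enterocyte_volume
    }
  }

  ev <- do.call(rbind, lapply(regimens, function(r) {
    data.frame(var = paste0(r$compound, ".gut"),
               time = r$start + (seq_len(r$n_doses) - 1) * r$interval,
               value = r$dose * 1000 / spec$compounds[[r$compound]]$mw,
               method = "add")
  }))
  ev$time <- round(ev$time, 6)
  ev <- ev[order(ev$time), ]
  times <- sort(unique(c(round(seq(0, duration, by = opts$dt), 6), ev$time)))

  sw <- spec$switches
  perps <- match(spec$perpetrators, cn)
  fi <- sw$pgp_fold_increase
  qh <- sys$hepatic_blood_flow; qv <- sys$villous_blood_flow
  vent <- sys$enterocyte_volume
  kdeg_li <- sys$kdeg[["liver"]]; kdeg_gut <- sys$kdeg[["gut"]]
  n_cmp <- length(pars)
  # integer state layout: 9 states per compound, then the two enzyme pools
  off <- (seq_len(n_cmp) - 1) * 9
  i_gut <- off + 1; i_ent <- off + 2; i_cen <- off + 3; i_per <- off + 4
  i_unab <- off + 5; i_gm <- off + 6; i_hm <- off + 7; i_rn <- off + 8
  i_form <- off + 9
  i_eli <- n_cmp * 9 + 1; i_egut <- n_cmp * 9 + 2
  link_par <- vapply(spec$metabolite_links, function(lk)
    match(lk$parent, cn), integer(1))
  link_met <- vapply(spec$metabolite_links, function(lk)
    match(lk$metabolite, cn), integer(1))
  clamp_idx <- if (!is.null(clamp))
    as.vector(vapply(match(names(clamp), cn), function(k)
      c(i_gut[k], i_ent[k], i_cen[k], i_per[k]), numeric(4))) else integer()
  # flatten per-compound constants for fast access
  P <- pars
  n_state <- length(sn)

  deriv <- function(t, y, parms) {
    dy <- numeric(n_state)
    e_li <- y[i_eli]; e_gut <- y[i_egut]

    # perpetrator driver concentrations (unbound, umol/L)
    amp_li <- amp_gut <- 0
    s3a_li <- s3a_gut <- s_pgp <- s_oat3 <- 0
    for (j in perps) {
      p <- P[[j]]
      cc <- max(y[i_cen[j]], 0) / p$vc
      ce <- max(y[i_ent[j]], 0) / vent
      cu_in <- p$fu * ((qh - qv) * cc + qv * ce) / qh
      cu_e <- p$fu_gut * ce
      cu_s <- p$fu * cc
      if (sw$cyp3a_induction && p$indmax > 1) {
        amp_li <- amp_li + (p$indmax - 1) * cu_in / (p$indc50 + cu_in)
        amp_gut <- amp_gut + (p$indmax - 1) * cu_e / (p$indc50 + cu_e)
      }
      if (!is.na(p$ki_cyp3a)) {
        s3a_li <- s3a_li + cu_in / p$ki_cyp3a
        s3a_gut <- s3a_gut + cu_e / p$ki_cyp3a
      }
      if (!is.na(p$ki_pgp)) s_pgp <- s_pgp + cu_e / p$ki_pgp
      if (!is.na(p$ki_oat3)) s_oat3 <- s_oat3 + cu_s / p$ki_oat3
    }
    inh3a_li <- if (sw$cyp3a_inhibition) 1 / (1 + s3a_li) else 1
    inh3a_gut <- if (sw$cyp3a_inhibition) 1 / (1 + s3a_gut) else 1
    inh_pgp <- if (sw$pgp_inhibition) 1 / (1 + s_pgp) else 1
    inh_oat3 <- if (sw$oat3_inhibition) 1 / (1 + s_oat3) else 1

    dy[i_eli] <- kdeg_li * (1 + amp_li - e_li)
    dy[i_egut] <- kdeg_gut * (1 + amp_gut - e_gut)

    formed <- numeric(length(link_par))
    for (k in seq_len(n_cmp)) {
      p <- P[[k]]
      a_gut <- y[i_gut[k]]
      cc <- y[i_cen[k]] / p$vc
      cp <- y[i_per[k]] / p$vp
      ce <- y[i_ent[k]] / vent
      cu_e <- p$fu_gut * max(ce, 0)

      j_abs <- p$ka * a_gut
      j_loss <- p$kloss * a_gut
      gutmet <- p$cl3a4_gut * e_gut * inh3a_gut * cu_e
      pgpflx <- p$cl_pgp_gut * fi * inh_pgp * cu_e

      clint_eff <- p$clint_u
      if (p$has_3a4)
        clint_eff[p$is_3a4] <- clint_eff[p$is_3a4] * e_li * inh3a_li
      cl_tot <- sum(clint_eff)
      eh <- p$fub * cl_tot / (qh + p$fub * cl_tot)
      # portal inflow reaches the liver via the enterocyte outflow term
      inlet <- (qh - qv) * p$bp * cc + qv * p$bp * ce
      hep_flux <- eh * inlet
      clr_eff <- p$cl_r * (1 - p$frac_clr_oat3 + p$frac_clr_oat3 * inh_oat3)

      dy[i_gut[k]] <- -(j_abs + j_loss) + pgpflx
      dy[i_ent[k]] <- j_abs + qv * p$bp * (cc - ce) - gutmet - pgpflx
      dy[i_cen[k]] <- (1 - eh) * inlet - qh * p$bp * cc -
        clr_eff * cc - p$cl_d * (cc - cp)
      dy[i_per[k]] <- p$cl_d * (cc - cp)
      dy[i_unab[k]] <- j_loss
      dy[i_gm[k]] <- gutmet
      dy[i_hm[k]] <- hep_flux
      dy[i_rn[k]] <- clr_eff * cc

      if (p$any_m2 && cl_tot > 0 && hep_flux != 0) {
        lk <- match(k, link_par)
        if (!is.na(lk)) formed[lk] <- hep_flux * sum(clint_eff * p$frac_m2) / cl_tot
      }
    }
    for (lk in seq_along(link_par)) {
      m <- link_met[lk]
      dy[i_cen[m]] <- dy[i_cen[m]] + formed[lk]
      dy[i_form[m]] <- dy[i_form[m]] + formed[lk]
    }
    if (length(clamp_idx)) dy[clamp_idx] <- 0
    list(dy)
  }

  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = opts$method, atol = opts$atol,
                      rtol = opts$rtol, events = list(data = ev),
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed; final state: ",
         paste(sprintf("%s=%.3g", sn, out[nrow(out), -1]), collapse = ", "))
  colnames(out) <- c("time", sn)
  structure(list(time = out[, "time"], states = out[, -1, drop = FALSE],
                 spec = spec, regimens = regimens, pars = pars),
            class = "sim_result")
}

#' Extract a concentration series from a simulation
#'
#' @param result A `sim_result` from [simulate_pbpk()].
#' @param compound Compound name.
#' @param compartment `"central"` (plasma, umol/L), `"peripheral"`,
#'   `"enterocyte"` or `"gut_lumen"` (the latter returned as amount, umol).
#' @return Numeric vector along `result$time`.
#' @export
conc_series <- function(result, compound, compartment = "central") {
  p <- result$pars[[compound]]
  if (is.null(p)) stop("unknown compound ", compound)
  st <- result$states
  switch(compartment,
         central = st[, paste0(compound, ".cen")] / p$vc,
         peripheral = st[, paste0(compound, ".per")] / p$vp,
         enterocyte = st[, paste0(compound, ".ent")] /
           result$spec$system$enterocyte_volume,
         gut_lumen = st[, paste0(compound, ".gut")],
         stop("unknown compartment ", compartment))
}

#' Relative enzyme-pool series
#'
#' @param result A `sim_result`.
#' @param pool `"liver"` or `"gut"` CYP3A4 pool.
#' @return E/E0 along `result$time`.
#' @export
enzyme_series <- function(result, pool = c("liver", "gut")) {
  pool <- match.arg(pool)
  result$states[, if (pool == "liver") "E_liver_CYP3A4" else "E_gut_CYP3A4"]
}

#' Mass-balance residuals of a simulation
#'
#' For each compound, compares cumulative input (dosed + formed, umol)
#' against the sum of compartment amounts and cumulative elimination by
#' route at the final time point.
#'
#' @param result A `sim_result`.
#' @return Data.frame with `compound`, `input_umol`, `accounted_umol`,
#'   `rel_error`.
#' @export
mass_balance <- function(result) {
  st <- result$states[nrow(result$states), ]
  rows <- lapply(names(result$pars), function(i) {
    dosed <- sum(vapply(result$regimens, function(r)
      if (r$compound == i) r$n_doses * r$dose * 1000 /
        result$spec$compounds[[i]]$mw else 0, numeric(1)))
    input <- dosed + st[[paste0(i, ".cum_formed")]]
    acct <- sum(st[paste0(i, c(".gut", ".ent", ".cen", ".per", ".cum_unabs",
                               ".cum_gutmet", ".cum_hepmet", ".cum_ren"))])
    data.frame(compound = i, input_umol = input, accounted_umol = acct,
               rel_error = if (input > 0) (acct - input) / input else 0)
  })
  do.call(rbind, rows)
}

#' Non-compartmental metrics over a time window
#'
#' Linear-trapezoid AUC plus Cmax/Tmax/Cmin of a compound's central plasma
#' concentration between `window[1]` and `window[2]` (window bounds are
#' interpolated onto the grid).
#'
#' @param result A `sim_result`.
#' @param compound Compound name.
#' @param window Length-2 numeric `(t0, t1)` in hours within the simulated
#'   range.
#' @return List with `auc` (umol*h/L), `cmax`, `cmin` (umol/L), `tmax` (h).
#' @export
pk_metrics <- function(result, compound, window = range(result$time)) {
  t <- result$time
  if (window[2] <= window[1]) stop("empty window")
  if (window[1] < min(t) || window[2] > max(t))
    stop("window outside simulated range")
  conc <- conc_series(result, compound)
  keep <- t > window[1] & t < window[2]
  tt <- c(window[1], t[keep], window[2])
  cc <- c(stats::approx(t, conc, window[1])$y, conc[keep],
          stats::approx(t, conc, window[2])$y)
  auc <- sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
  list(auc = auc, cmax = max(cc), tmax = tt[which.max(cc)], cmin = min(cc))
}
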