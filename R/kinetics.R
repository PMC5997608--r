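# Two-guild feast-famine storage/growth kinetics.
#
# Guild 1 ("storers") takes up acetate and channels it entirely into PHB
# during the feast (double growth limitation: no ammonium present, so no
# growth on external substrate), then grows on the stored PHB when ammonium
# is fed at the start of the famine. Guild 2 ("non-storers") can only grow
# when external acetate and ammonium co-occur. Uptake is Monod in substrate
# with a classical substrate-inhibition term and a storage-capacity
# saturation term; maintenance respiration draws on PHB when present, else
# on biomass, so that carbon and electron balances close identically.

#' Kinetic parameter set for the two-guild storage model
#'
#' All organic concentrations in Cmmol/L, ammonium in mmol N/L, time in h.
#'
#' @param q_s_max maximum specific acetate uptake rate of storers,
#'   Cmol Ac/Cmol X/h. The calibrated default reproduces a feast-mean
#'   specific uptake of about 1.05 under pulsed feeding.
#' @param K_S substrate half-saturation, Cmmol/L.
#' @param K_I substrate-inhibition constant, Cmmol/L (`Inf` disables
#'   inhibition).
#' @param Y_PS_max maximum storage yield, Cmol PHB/Cmol Ac (<= 1).
#' @param f_phb_max storage capacity, Cmol PHB/Cmol X. The default 8 makes a
#'   PHB content of ~87 wt% attainable.
#' @param alpha exponent of the capacity-saturation term
#'   (1 - (f/f_max)^alpha).
#' @param mu_max maximum specific growth rate on stored PHB, 1/h.
#' @param K_f half-saturation of growth in the cellular PHB fraction,
#'   Cmol PHB/Cmol X.
#' @param Y_X_PHB growth yield on PHB, Cmol X/Cmol PHB (<= 1).
#' @param K_N ammonium half-saturation, mmol N/L.
#' @param n_N nitrogen content of biomass, mol N/Cmol X (0.2 for
#'   CH1.8O0.5N0.2).
#' @param m_O2 maintenance respiration, mmol O2/Cmol X/h.
#' @param mu_max_ns maximum specific growth rate of non-storers on external
#'   acetate, 1/h (requires ammonium).
#' @param Y_X_S non-storer growth yield on acetate, Cmol X/Cmol Ac.
#' @param q_ns_ox non-storer overflow/maintenance substrate oxidation,
#'   Cmol Ac/Cmol X/h: nitrogen-starved heterotrophs keep oxidising
#'   external acetate to CO2 without growth, so an unselected community
#'   wastes feast carbon that storers would otherwise bank.
#' @param K_m_phb smoothing constant (Cmmol/L) for the switch of maintenance
#'   between PHB and biomass oxidation.
#' @return An object of class `kinetic_params` (a validated named list with
#'   the degrees of reduction of acetate, PHB and biomass attached).
#' @seealso [reaction_rates()], [calibrate_kinetics()]
#' @export
kinetic_params <- function(q_s_max = 1.80,
                           K_S = 1,
                           K_I = 60,
                           Y_PS_max = 0.85,
                           f_phb_max = 8,
                           alpha = 4,
                           mu_max = 0.2,
                           K_f = 0.1,
                           Y_X_PHB = 0.70,
                           K_N = 0.05,
                           n_N = 0.2,
                           m_O2 = 0.03,
                           mu_max_ns = 0.45,
                           Y_X_S = 0.5,
                           q_ns_ox = 0.30,
                           K_m_phb = 0.5) {
  p <- list(q_s_max = q_s_max, K_S = K_S, K_I = K_I, Y_PS_max = Y_PS_max,
            f_phb_max = f_phb_max, alpha = alpha, mu_max = mu_max, K_f = K_f,
            Y_X_PHB = Y_X_PHB, K_N = K_N, n_N = n_N, m_O2 = m_O2,
            mu_max_ns = mu_max_ns, Y_X_S = Y_X_S, q_ns_ox = q_ns_ox,
            K_m_phb = K_m_phb)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && !is.na(v),
                logical(1))
  if (!all(num)) stop("kinetic parameters must be single numeric values")
  pos <- setdiff(names(p), c("K_I", "q_ns_ox"))
  if (p$q_ns_ox < 0) stop("q_ns_ox must be non-negative")
  if (any(unlist(p[pos]) <= 0)) stop("kinetic parameters must be positive")
  if (p$K_I <= 0) stop("K_I must be positive (use Inf for no inhibition)")
  if (p$Y_PS_max > 1) stop("Y_PS_max > 1 violates the carbon balance")
  # electron feasibility: gamma_S = 4, gamma_P = 4.5, so storage yields at
  # or above 8/9 would bank more electrons in PHB than acetate supplies
  if (p$Y_PS_max >= 4 / 4.5)
    stop("Y_PS_max >= 0.889 (= gamma_S/gamma_P) captures more electrons ",
         "in PHB than the substrate carries")
  if (p$Y_X_PHB > 1) stop("Y_X_PHB > 1 violates the carbon balance")
  if (p$Y_X_S > 1) stop("Y_X_S > 1 violates the carbon balance")
  p$gamma_S <- degree_of_reduction(acetate_formula())
  p$gamma_P <- degree_of_reduction(phb_formula())
  p$gamma_X <- degree_of_reduction(biomass_formula())
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  show <- c("q_s_max", "K_S", "K_I", "Y_PS_max", "f_phb_max", "alpha",
            "mu_max", "K_f", "Y_X_PHB", "K_N", "m_O2", "mu_max_ns", "Y_X_S")
  for (nm in show) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Reaction rates of the two-guild storage model
#'
#' Evaluates all conversion rates at one state. The returned oxygen uptake
#' rate follows from the electron balance
#' `4 OUR = gamma_S * r_S - gamma_P * dPHB/dt - gamma_X * dX/dt`
#' and the CO2 evolution rate from the carbon balance, so both balances
#' close identically at every evaluation.
#'
#' @param state named numeric (or list) with components `S` (acetate,
#'   Cmmol/L), `X_st` (storer biomass, Cmmol/L), `X_ns` (non-storer biomass,
#'   Cmmol/L), `PHB` (Cmmol/L), `NH4` (mmol N/L). All non-negative.
#' @param params a [kinetic_params()] object.
#' @return A list of class `rate_vector` with per-hour derivatives `dS`,
#'   `dX_st`, `dX_ns`, `dPHB`, `dNH4`, plus `OUR` (mmol O2/L/h, >= 0),
#'   `CO2` (Cmmol/L/h, >= 0) and the underlying gross fluxes.
#' @export
reaction_rates <- function(state, params) {
  if (!inherits(params, "kinetic_params")) stop("params must be kinetic_params")
  s <- as.list(state)
  need <- c("S", "X_st", "X_ns", "PHB", "NH4")
  if (!all(need %in% names(s))) stop("state needs S, X_st, X_ns, PHB, NH4")
  v <- unlist(s[need])
  if (any(v < -1e-9)) stop("negative state component: ",
                           paste(need[v < -1e-9], collapse = ", "))
  rate_vector(pmax(v, 0), params)
}

# internal, unchecked RHS core shared with the ODE integrator
rate_vector <- function(y, p) {
  S <- y[["S"]]; Xst <- y[["X_st"]]; Xns <- y[["X_ns"]]
  PHB <- y[["PHB"]]; NH4 <- y[["NH4"]]

  monod_S <- S / (p$K_S + S)
  inhib <- if (is.finite(p$K_I)) p$K_I / (p$K_I + S) else 1
  n_lim <- NH4 / (p$K_N + NH4)

  # storers: uptake -> storage (feast), growth on PHB when N present
  f_st <- if (Xst > 0) PHB / Xst else 0
  cap <- max(0, 1 - (min(f_st, p$f_phb_max) / p$f_phb_max)^p$alpha)
  q_s <- p$q_s_max * monod_S * inhib * cap
  r_upt_st <- q_s * Xst                      # Cmmol Ac/L/h
  r_P_form <- p$Y_PS_max * r_upt_st
  mu_st <- p$mu_max * (f_st / (p$K_f + f_st)) * n_lim
  r_X_st <- mu_st * Xst
  r_P_cons <- r_X_st / p$Y_X_PHB

  # non-storers: growth only when external substrate and ammonium co-occur;
  # overflow oxidation of acetate continues regardless of nitrogen
  mu_ns <- p$mu_max_ns * monod_S * inhib * n_lim
  r_X_ns <- mu_ns * Xns
  r_ox_ns <- p$q_ns_ox * monod_S * inhib * Xns
  r_upt_ns <- r_X_ns / p$Y_X_S + r_ox_ns

  # maintenance: oxidise PHB when present (smooth switch), else biomass
  phi <- PHB / (PHB + p$K_m_phb)
  r_m_P <- phi * (4 / p$gamma_P) * p$m_O2 * Xst
  r_m_Xst <- (1 - phi) * (4 / p$gamma_X) * p$m_O2 * Xst
  r_m_Xns <- (4 / p$gamma_X) * p$m_O2 * Xns

  dS <- -(r_upt_st + r_upt_ns)
  dX_st <- r_X_st - r_m_Xst
  dX_ns <- r_X_ns - r_m_Xns
  dPHB <- r_P_form - r_P_cons - r_m_P
  dNH4 <- -p$n_N * (r_X_st + r_X_ns)

  CO2 <- (1 - p$Y_PS_max) * r_upt_st +
    (1 / p$Y_X_PHB - 1) * r_X_st +
    (1 / p$Y_X_S - 1) * r_X_ns + r_ox_ns +
    r_m_P + r_m_Xst + r_m_Xns

  OUR <- (p$gamma_S * (r_upt_st + r_upt_ns) -
            p$gamma_P * dPHB - p$gamma_X * (dX_st + dX_ns)) / 4

  structure(list(dS = dS, dX_st = dX_st, dX_ns = dX_ns, dPHB = dPHB,
                 dNH4 = dNH4, OUR = OUR, CO2 = CO2,
                 r_uptake = r_upt_st + r_upt_ns, r_storage = r_P_form,
                 r_phb_consumption = r_P_cons + r_m_P,
                 r_growth = r_X_st + r_X_ns),
            class = "rate_vector")
}
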