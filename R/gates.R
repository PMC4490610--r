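#' AND gate model (HrpR/HrpS two-activator promoter)
#'
#' Steady-state predictor for the sigma-54 enhancer-dependent AND gate:
#' two input devices independently express the enhancer-binding proteins
#' (HrpS driven by arabinose/pBAD, HrpR by rhamnose/pRHAB), which jointly
#' activate the weak pHrpL output promoter. Output is modelled as the product
#' of the two normalised Hill activations scaled into the pHrpL range, with a
#' linear plasmid copy-number factor on the reporter module:
#' \deqn{Y(x_a, x_r) = G_0 + G_{max} \frac{copy}{copy_{ref}} a_S(x_a) a_R(x_r)}
#' Activator-module copy number does not appear: activators accumulate above
#' the saturation level of pHrpL, so only reporter-module dosage matters.
#'
#' @param device_s [input_device()] driving HrpS (input A).
#' @param device_r [input_device()] driving HrpR (input B).
#' @param G0 Basal pHrpL output (au), `>= 0`.
#' @param Gmax Maximal pHrpL output at the reference copy number (au), `> 0`.
#' @param reporter_copy Plasmid copy number carrying the pHrpL-reporter module.
#' @param reference_copy Copy number at which `Gmax` was calibrated.
#' @return An object of class `and_gate_model`.
#' @export
and_gate <- function(device_s, device_r, G0 = 50, Gmax = 1000,
                     reporter_copy = 5, reference_copy = 5) {
  stopifnot(inherits(device_s, "input_device"),
            inherits(device_r, "input_device"))
  if (G0 < 0 || Gmax <= 0) stop("need G0 >= 0 and Gmax > 0.", call. = FALSE)
  if (reporter_copy < 1 || reference_copy < 1)
    stop("plasmid copy numbers must be >= 1.", call. = FALSE)
  structure(list(device_s = device_s, device_r = device_r, G0 = G0,
                 Gmax = Gmax, reporter_copy = reporter_copy,
                 reference_copy = reference_copy),
            class = "and_gate_model")
}

#' Predict AND gate output
#'
#' @param model An [and_gate()] model.
#' @param xa Arabinose (input A) concentration, mol/L.
#' @param xr Rhamnose (input B) concentration, mol/L.
#' @param activator_share Fraction of HrpRS activators available to this
#'   pHrpL module (1 = no competition; see [half_adder_predict()]).
#' @return Predicted output (au). Vectorised over `xa`/`xr`.
#' @export
and_predict <- function(model, xa, xr, activator_share = 1) {
  stopifnot(inherits(model, "and_gate_model"))
  aS <- normalized_activation(effective_hill(model$device_s), xa)
  aR <- normalized_activation(effective_hill(model$device_r), xr)
  model$G0 + model$Gmax * (model$reporter_copy / model$reference_copy) *
    activator_share * aS * aR
}

#' Copy-number amplification of the AND gate reporter module
#'
#' Ratio of basal-subtracted AND outputs when the pHrpL-reporter module sits
#' on a high- versus low-copy plasmid, activator modules held fixed. Reporter
#' output scales linearly with promoter availability, so the ratio equals
#' `copy_high / copy_low`; moving the activator modules between copy classes
#' leaves the output unchanged (activator saturation).
#'
#' @param model An [and_gate()] model.
#' @param copy_high,copy_low Reporter-module copy numbers to compare.
#' @param xa,xr Inducer concentrations at which to evaluate (default:
#'   saturating logic inputs).
#' @return Dimensionless fold ratio.
#' @export
copy_amplification_ratio <- function(model, copy_high = 100, copy_low = 5,
                                     xa = logic_inputs()["a"],
                                     xr = logic_inputs()["b"]) {
  stopifnot(inherits(model, "and_gate_model"))
  if (copy_high < 1 || copy_low < 1)
    stop("plasmid copy numbers must be >= 1.", call. = FALSE)
  hi <- model; hi$reporter_copy <- copy_high
  lo <- model; lo$reporter_copy <- copy_low
  unname((and_predict(hi, xa, xr) - hi$G0) /
           (and_predict(lo, xa, xr) - lo$G0))
}

#' OR gate model (tandem promoters or dual cassettes)
#'
#' The OR gate expresses one reporter from two inducible promoters, either as
#' tandem promoters in one transcript (designs I and II, differing in
#' promoter order) or as two discrete expression cassettes (design III).
#' Functional architectures are additive: total output is the sum of the two
#' single-promoter Hill outputs, optionally soft-capped to represent
#' saturation of the expression machinery at very high induction. Design II
#' (pRHAB upstream of pBAD) is non-functional on the arabinose arm: the
#' dual-function regulator AraC, when overexpressed without arabinose, stays
#' bound to its operators and loops the pBAD promoter, silencing the
#' transcript; the model returns only the pRHAB arm.
#'
#' @param device_a,device_b Input [input_device()]s (arabinose and rhamnose
#'   arms).
#' @param architecture One of `"dual_cassette_design_III"`,
#'   `"tandem_design_I"`, `"tandem_design_II"`.
#' @param saturation_cap Optional maximal summed output (au); `NULL` (the
#'   default) disables the cap.
#' @return An object of class `or_gate_model`.
#' @export
or_gate <- function(device_a, device_b,
                    architecture = c("dual_cassette_design_III",
                                     "tandem_design_I", "tandem_design_II"),
                    saturation_cap = NULL) {
  stopifnot(inherits(device_a, "input_device"),
            inherits(device_b, "input_device"))
  architecture <- match.arg(architecture)
  if (!is.null(saturation_cap) && saturation_cap <= 0)
    stop("saturation_cap must be > 0 when given.", call. = FALSE)
  structure(list(device_a = device_a, device_b = device_b,
                 architecture = architecture,
                 saturation_cap = saturation_cap),
            class = "or_gate_model")
}

#' Predict OR gate output
#'
#' @param model An [or_gate()] model.
#' @param xa,xr Inducer concentrations (mol/L).
#' @return Predicted output (au).
#' @export
or_predict <- function(model, xa, xr) {
  stopifnot(inherits(model, "or_gate_model"))
  yb <- device_eval(model$device_b, xr)
  if (model$architecture == "tandem_design_II") return(yb)
  out <- device_eval(model$device_a, xa) + yb
  if (!is.null(model$saturation_cap))
    out <- out * model$saturation_cap / (out + model$saturation_cap)
  out
}

#' Operator-site repression model (lambda CI roadblock)
#'
#' Repression by lambda CI repressor bound to operator sites placed
#' downstream of the transcription start site, acting as a roadblock to RNA
#' polymerase elongation. Transmission is a descending Hill function of the
#' repressor level with a leak floor:
#' \deqn{f(cl) = \epsilon + (1-\epsilon) / (1 + (cl/K_{eff})^h)}
#' where `K_eff = Kr * site_multiplier(n_sites) * distance_multiplier`.
#' A single operator site gives negligible repression (site multiplier 250);
#' two sites of perfect dyad symmetry repress efficiently (multiplier 1);
#' four sites also bind efficiently but the construct fails for a different
#' reason — the accumulated 5'-UTR hairpins block expression in every
#' condition (see [utr_penalty()]). Sites engineered far from the
#' transcription start site need more repressor to stall the polymerase
#' (distal multiplier 5).
#'
#' @param n_sites Number of lambda CI operator sites: 1, 2 or 4.
#' @param Kr Half-repression repressor level (normalised repressor units).
#' @param h Repression Hill coefficient.
#' @param leak_floor Minimal residual transmission in `[0, 1)`.
#' @param distance_class `"proximal"` (immediately downstream of the TSS) or
#'   `"distal"`.
#' @return An object of class `repression_model`.
#' @export
repression_model <- function(n_sites = 2, Kr = 0.15, h = 2,
                             leak_floor = 0.02,
                             distance_class = c("proximal", "distal")) {
  distance_class <- match.arg(distance_class)
  if (!n_sites %in% c(1, 2, 4))
    stop("unsupported operator configuration: n_sites must be 1, 2 or 4.",
         call. = FALSE)
  if (Kr <= 0 || h <= 0) stop("need Kr > 0 and h > 0.", call. = FALSE)
  if (leak_floor < 0 || leak_floor >= 1)
    stop("leak_floor must be in [0, 1).", call. = FALSE)
  structure(list(n_sites = n_sites, Kr = Kr, h = h, leak_floor = leak_floor,
                 distance_class = distance_class),
            class = "repression_model")
}

site_multiplier <- function(n_sites) {
  switch(as.character(n_sites), "1" = 250, "2" = 1, "4" = 1,
         stop("unsupported operator configuration: n_sites must be 1, 2 or 4.",
              call. = FALSE))
}

#' Residual transmission through a repressed hybrid promoter
#'
#' @param model A [repression_model()].
#' @param cl Repressor level (normalised units, `>= 0`). Vectorised.
#' @return Transmission factor in `(0, 1]`.
#' @export
repression_factor <- function(model, cl) {
  stopifnot(inherits(model, "repression_model"))
  if (any(cl < 0)) stop("repressor level cl must be >= 0.", call. = FALSE)
  k_eff <- model$Kr * site_multiplier(model$n_sites) *
    if (model$distance_class == "distal") 5 else 1
  eps <- model$leak_floor
  eps + (1 - eps) / (1 + (cl / k_eff)^model$h)
}

#' 5'-UTR hairpin expression penalty
#'
#' Multiplicative expression penalty for consecutive stem-loop (hairpin)
#' structures in the 5' untranslated region immediately downstream of the
#' transcription start site, which act as pseudo transcription terminators or
#' sequester the ribosome binding site. Modelled as a logistic switch in the
#' hairpin count: `1 / (1 + exp(k * (h - h0)))`. With the defaults
#' (`h0 = 5`, `k = 2`), three hairpins — the count left after directed
#' evolution of the operator region — pass essentially full expression
#' (0.982) while seven consecutive hairpins block it (0.018).
#'
#' @param hairpin_count Number of consecutive 5'-UTR hairpins, `>= 0`.
#' @param h0 Penalty midpoint (hairpins).
#' @param k Logistic steepness (per hairpin).
#' @return Multiplier in `(0, 1]`. Vectorised over `hairpin_count`.
#' @export
utr_penalty <- function(hairpin_count, h0 = 5, k = 2) {
  if (any(hairpin_count < 0))
    stop("hairpin_count must be >= 0.", call. = FALSE)
  1 / (1 + exp(k * (hairpin_count - h0)))
}

#' Competition shares between pHrpL modules on different plasmids
#'
#' When two pHrpL promoters reside on plasmids of different copy number, they
#' compete for the limited pool of HrpRS transcription activators. The share
#' captured by each module follows copy-number-weighted partitioning with
#' exponent `gamma`: `w_low = c_low^gamma / (c_low^gamma + c_high^gamma)`.
#' `gamma = 0` means no copy bias (equal shares); `gamma = 1` is proportional
#' partitioning.
#'
#' @param copy_low,copy_high Plasmid copy numbers (`>= 1`).
#' @param gamma Competition exponent, `>= 0`.
#' @return Named numeric vector `c(w_low, w_high)`, summing to 1.
#' @export
competition_shares <- function(copy_low = 5, copy_high = 100, gamma = 0.6) {
  if (copy_low < 1 || copy_high < 1)
    stop("plasmid copy numbers must be >= 1.", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0.", call. = FALSE)
  wl <- copy_low^gamma / (copy_low^gamma + copy_high^gamma)
  c(w_low = wl, w_high = 1 - wl)
}

#' Composite gate model (layered AND / OR / NOT logic)
#'
#' Parameter container for the layered circuits: NIMPLY, XOR, half adder and
#' half subtractor. The AND sub-model drives lambda CI synthesis from pHrpL
#' (level `cl_max` at full activation, normalised units); the OR arms express
#' the reporter from hybrid promoters carrying `n_sites` CI operators with
#' `utr_hairpins` residual stem-loops; activator competition between the two
#' pHrpL modules is governed by `competition_gamma` and the plasmid copy
#' numbers.
#'
#' @param and_gate An [and_gate()] model (activator/repressor driver).
#' @param device_a,device_b OR-arm [input_device()]s; defaults: the AND
#'   gate's input devices re-used as reporter arms.
#' @param repression A [repression_model()].
#' @param cl_max Lambda CI level at full AND activation (normalised), `> 0`.
#' @param competition_gamma Copy-number competition exponent.
#' @param copy_low,copy_high Copy numbers of the two pHrpL-module plasmids.
#' @param utr_hairpins Hairpin count of the OR-arm 5'-UTRs.
#' @param rbs_alpha_out RBS scale factor of the reporter output stage.
#' @return An object of class `composite_gate_model`.
#' @export
composite_gate <- function(and_gate, device_a = and_gate$device_s,
                           device_b = and_gate$device_r,
                           repression = repression_model(),
                           cl_max = 1, competition_gamma = 0.6,
                           copy_low = 5, copy_high = 100,
                           utr_hairpins = 3, rbs_alpha_out = 1) {
  stopifnot(inherits(and_gate, "and_gate_model"),
            inherits(repression, "repression_model"))
  if (cl_max <= 0) stop("cl_max must be > 0.", call. = FALSE)
  if (copy_low < 1 || copy_high < 1)
    stop("plasmid copy numbers must be >= 1.", call. = FALSE)
  structure(list(and_gate = and_gate, device_a = device_a,
                 device_b = device_b, repression = repression,
                 cl_max = cl_max, competition_gamma = competition_gamma,
                 copy_low = copy_low, copy_high = copy_high,
                 utr_hairpins = utr_hairpins, rbs_alpha_out = rbs_alpha_out),
            class = "composite_gate_model")
}

or_arm_sum <- function(model, xa, xr) {
  device_eval(model$device_a, xa) + device_eval(model$device_b, xr)
}

#' Predict NIMPLY gate output (B AND NOT A)
#'
#' OR-gate reporter transcript gated by lambda CI produced from a separate
#' pBAD cassette: CI level is `cl_max * aA(xa)`, so the reporter is expressed
#' only when input B (rhamnose) is present without input A (arabinose).
#' Output = `rbs_alpha * (arm sum) * repression_factor(cl) *
#' utr_penalty(hairpins)`.
#'
#' @param model A [composite_gate()] model.
#' @param xa,xr Inducer concentrations (mol/L).
#' @param rbs_alpha Output-stage RBS factor; defaults to the model's.
#' @return Predicted output (au).
#' @export
nimply_predict <- function(model, xa, xr, rbs_alpha = model$rbs_alpha_out) {
  stopifnot(inherits(model, "composite_gate_model"))
  aA <- normalized_activation(effective_hill(model$and_gate$device_s), xa)
  cl <- model$cl_max * aA
  rbs_alpha * or_arm_sum(model, xa, xr) *
    repression_factor(model$repression, cl) *
    utr_penalty(model$utr_hairpins)
}

#' Predict XOR gate output (dual-cassette design)
#'
#' Two discrete hybrid-promoter cassettes (pBAD-CI and pRHAB-CI operators)
#' express the reporter; lambda CI is synthesised by the AND gate
#' (`cl = cl_max * aS(xa) * aR(xr)`), shutting the reporter off only when
#' both inputs are present. With `competition_on`, the CI module receives
#' only the high-copy competition share of the activators.
#'
#' @param model A [composite_gate()] model.
#' @param xa,xr Inducer concentrations (mol/L).
#' @param competition_on Logical: apply activator competition between the two
#'   pHrpL modules (use `TRUE` inside a half adder, `FALSE` for a standalone
#'   XOR whose circuit has a single pHrpL module).
#' @return Predicted output (au).
#' @export
xor_predict <- function(model, xa, xr, competition_on = FALSE) {
  stopifnot(inherits(model, "composite_gate_model"))
  aS <- normalized_activation(effective_hill(model$and_gate$device_s), xa)
  aR <- normalized_activation(effective_hill(model$and_gate$device_r), xr)
  w_high <- if (competition_on)
    competition_shares(model$copy_low, model$copy_high,
                       model$competition_gamma)[["w_high"]]
  else 1
  cl <- model$cl_max * aS * aR * w_high
  model$rbs_alpha_out * or_arm_sum(model, xa, xr) *
    repression_factor(model$repression, cl) *
    utr_penalty(model$utr_hairpins)
}

#' Predict half-adder outputs (CARRY = AND, SUM = XOR)
#'
#' The half adder runs the AND gate (GFP CARRY, pHrpL-GFP on the low-copy
#' plasmid) in parallel with the XOR gate (RFP SUM; lambda CI from pHrpL on
#' the high-copy plasmid). Both pHrpL modules compete for HrpRS activators:
#' the CARRY module receives share `w_low`, the CI module `w_high`
#' (see [competition_shares()]), so the standalone-AND to half-adder CARRY
#' ratio (basal-subtracted) is `1 / w_low = 1 + (c_high/c_low)^gamma`.
#'
#' @param model A [composite_gate()] model.
#' @param xa,xr Inducer concentrations (mol/L).
#' @return List with `sum_out` and `carry_out` (au).
#' @export
half_adder_predict <- function(model, xa, xr) {
  stopifnot(inherits(model, "composite_gate_model"))
  w <- competition_shares(model$copy_low, model$copy_high,
                          model$competition_gamma)
  ag <- model$and_gate
  carry <- and_predict(ag, xa, xr, activator_share = w[["w_low"]])
  sum_out <- xor_predict(model, xa, xr, competition_on = TRUE)
  list(sum_out = sum_out, carry_out = carry)
}

#' Predict half-subtractor outputs (DIFFERENCE = XOR, BORROW = A AND NOT B)
#'
#' Obtained from the half adder by replacing the pHrpL-GFP CARRY module with
#' a pBAD-CI hybrid cassette on the low-copy plasmid: GFP (BORROW) is
#' expressed from pBAD and silenced by AND-driven lambda CI, yielding
#' `borrow = hill_a(xa) * repression_factor(cl) * utr_penalty(hairpins)`.
#' RFP (DIFFERENCE) is the XOR output. Because this circuit has a single
#' pHrpL module (pHrpL-CI), activator competition is off by default.
#'
#' @param model A [composite_gate()] model.
#' @param xa,xr Inducer concentrations (mol/L).
#' @param competition_on Logical; `FALSE` by default (single pHrpL module).
#' @return List with `difference_out` and `borrow_out` (au).
#' @export
half_subtractor_predict <- function(model, xa, xr, competition_on = FALSE) {
  stopifnot(inherits(model, "composite_gate_model"))
  aS <- normalized_activation(effective_hill(model$and_gate$device_s), xa)
  aR <- normalized_activation(effective_hill(model$and_gate$device_r), xr)
  w_high <- if (competition_on)
    competition_shares(model$copy_low, model$copy_high,
                       model$competition_gamma)[["w_high"]]
  else 1
  cl <- model$cl_max * aS * aR * w_high
  borrow <- device_eval(model$device_a, xa) *
    repression_factor(model$repression, cl) *
    utr_penalty(model$utr_hairpins)
  diff_out <- xor_predict(model, xa, xr, competition_on = competition_on)
  list(difference_out = diff_out, borrow_out = borrow)
}

#' Default calibrated parameter set
#'
#' The package's reference calibration for all worked examples and
#' acceptance computations: pBAD (A = 30, B = 3000 au, C = 1.1e-4 M,
#' n = 2) and pRHAB (A = 25, B = 3500 au, C = 5e-4 M, n = 1.8) input
#' devices; pHrpL AND stage G0 = 50 au, Gmax = 1000 au; repression
#' eps = 0.02, Kr = 0.15, h = 2 with two proximal operator sites; UTR
#' logistic h0 = 5, k = 2 with 3 residual hairpins; competition gamma = 0.6
#' over copy numbers 5 (low) and 100 (high); cl_max = 1.
#'
#' @return `default_input_devices()`: named list of two [input_device()]s.
#' @export
default_input_devices <- function() {
  list(pBAD = input_device("pBAD", "arabinose",
                           hill_params(A = 30, B = 3000, C = 1.1e-4, n = 2)),
       pRHAB = input_device("pRHAB", "rhamnose",
                            hill_params(A = 25, B = 3500, C = 5e-4, n = 1.8)))
}

#' @rdname default_input_devices
#' @param ... Overrides passed to [and_gate()], [or_gate()] or
#'   [composite_gate()].
#' @export
default_and_gate <- function(...) {
  dev <- default_input_devices()
  and_gate(dev$pBAD, dev$pRHAB, ...)
}

#' @rdname default_input_devices
#' @export
default_or_gate <- function(...) {
  dev <- default_input_devices()
  or_gate(dev$pBAD, dev$pRHAB, ...)
}

#' @rdname default_input_devices
#' @export
default_composite_gate <- function(...) {
  composite_gate(default_and_gate(), ...)
}

#' Saturating logic input levels
#'
#' The two-input induction levels used for four-condition digital
#' characterisation: 7 mM arabinose (input A) and 28 mM rhamnose (input B),
#' in mol/L.
#'
#' @return Named numeric vector `c(a = 7e-3, b = 2.8e-2)`.
#' @export
logic_inputs <- function() c(a = 7e-3, b = 2.8e-2)
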