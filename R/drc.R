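#' Cassette-level circuit description
#'
#' Describes a layered circuit as plasmids carrying ordered expression
#' cassettes. Each cassette is one transcript: one or more promoters (two or
#' more = tandem promoters), optional repressor operator sites attached to
#' each promoter, an RBS, a coding sequence and a terminator flag. Input
#' (inducible) promoters declare their `inducer`; regulators that act as both
#' activator and repressor (e.g. AraC) set `regulator_dual_function`.
#'
#' @param plasmids List of `list(id, copy_class)` with `copy_class` one of
#'   `"low"`, `"high"`.
#' @param cassettes List of cassettes in physical 5'->3' order per plasmid:
#'   `list(plasmid, promoters = list(list(name, sigma_class, regulator,
#'   regulator_dual_function, inducer, operator_sites)), rbs = list(label,
#'   alpha), cds, terminator)`.
#' @param orthogonality_evidence Named logical list keyed by sorted device
#'   pairs, e.g. `list("pBAD|pRHAB" = TRUE)`.
#' @return An object of class `circuit_design`.
#' @export
circuit_design <- function(plasmids, cassettes,
                           orthogonality_evidence = list()) {
  for (p in plasmids) {
    if (is.null(p$id) || is.null(p$copy_class) ||
        !p$copy_class %in% c("low", "high"))
      stop("each plasmid needs an id and copy_class in {low, high}.",
           call. = FALSE)
  }
  ids <- vapply(plasmids, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("plasmid ids must be unique.", call. = FALSE)
  cassettes <- lapply(cassettes, normalise_cassette, plasmid_ids = ids)
  structure(list(plasmids = plasmids, cassettes = cassettes,
                 orthogonality_evidence = orthogonality_evidence),
            class = "circuit_design")
}

normalise_cassette <- function(cs, plasmid_ids) {
  if (is.null(cs$plasmid) || !cs$plasmid %in% plasmid_ids)
    stop("cassette references unknown plasmid '", cs$plasmid, "'.",
         call. = FALSE)
  if (is.null(cs$promoters) || !length(cs$promoters))
    stop("cassette on plasmid '", cs$plasmid, "' has no promoter.",
         call. = FALSE)
  cs$promoters <- lapply(cs$promoters, function(pr) {
    if (is.null(pr$name)) stop("promoter needs a name.", call. = FALSE)
    if (is.null(pr$sigma_class)) pr$sigma_class <- "sigma70"
    if (!pr$sigma_class %in% c("sigma70", "sigma54"))
      stop("sigma_class must be sigma70 or sigma54.", call. = FALSE)
    if (is.null(pr$regulator_dual_function)) pr$regulator_dual_function <- FALSE
    if (is.null(pr$operator_sites)) pr$operator_sites <- list()
    pr
  })
  if (is.null(cs$rbs)) cs$rbs <- list(label = "strong", alpha = 1)
  if (is.null(cs$rbs$alpha)) cs$rbs$alpha <- 1
  if (is.null(cs$cds)) cs$cds <- ""
  if (is.null(cs$terminator)) cs$terminator <- TRUE
  cs
}

violation <- function(rule_id, severity, message, plasmid, cassette) {
  data.frame(rule_id = rule_id, severity = severity, message = message,
             plasmid = plasmid, cassette = as.integer(cassette),
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(rule_id = character(), severity = character(),
             message = character(), plasmid = character(),
             cassette = integer(), stringsAsFactors = FALSE)
}

input_promoter_names <- function(design) {
  nm <- character()
  for (cs in design$cassettes)
    for (pr in cs$promoters)
      if (!is.null(pr$inducer) && !is.na(pr$inducer)) nm <- c(nm, pr$name)
  unique(nm)
}

first_cassette_with_promoter <- function(design, pname) {
  for (k in seq_along(design$cassettes))
    for (pr in design$cassettes[[k]]$promoters)
      if (pr$name == pname)
        return(list(plasmid = design$cassettes[[k]]$plasmid, cassette = k))
  list(plasmid = NA_character_, cassette = NA_integer_)
}

#' Design-rule checks for layered genetic circuits
#'
#' Each check audits one genetic-context failure mode and returns a table of
#' violations (possibly empty). [run_drc()] aggregates all of them. The
#' failure-mode-to-check mapping is listed by [drc_rule_table()].
#'
#' * `check_crosstalk` — every pair of distinct input devices must carry
#'   pairwise orthogonality evidence (warning).
#' * `check_sigma54_proximity` — two sigma-54 promoters on the same plasmid:
#'   the downstream one can be switched on constitutively through DNA
#'   supercoiling; insulate on separate plasmids (error, flagged on the
#'   downstream cassette).
#' * `check_tandem_interference` — a promoter whose regulator is
#'   dual-function (activator/repressor, e.g. AraC) placed downstream in a
#'   tandem pair is silenced by regulator-mediated DNA looping (error).
#' * `check_operator_repeats` — four or more identical operator sites in one
#'   transcript block expression through 5'-UTR structure (error); one site
#'   cannot repress fully (warning); identical sites repeated across both
#'   arms of a tandem transcript risk pronounced UTR effects (warning).
#' * `check_rbs_balance` — input modules feeding an AND/OR gate should have
#'   maximal outputs `alpha * (A + B)` within `max_ratio` of each other
#'   (warning); a repressed (NOT-stage) transcript with a strong RBS
#'   (`alpha > 0.5`) is leak-prone (warning).
#'
#' @param design A [circuit_design()].
#' @return A data.frame of violations with columns `rule_id`, `severity`,
#'   `message`, `plasmid`, `cassette`.
#' @export
check_crosstalk <- function(design) {
  stopifnot(inherits(design, "circuit_design"))
  devs <- sort(input_promoter_names(design))
  out <- no_violations()
  if (length(devs) < 2L) return(out)
  for (i in seq_len(length(devs) - 1L)) for (j in seq(i + 1L, length(devs))) {
    key <- paste(devs[i], devs[j], sep = "|")
    if (!isTRUE(design$orthogonality_evidence[[key]])) {
      ref <- first_cassette_with_promoter(design, devs[i])
      out <- rbind(out, violation(
        "crosstalk_unevidenced", "warning",
        sprintf("no pairwise orthogonality evidence for input devices %s and %s; characterise each device against the other's inducer.",
                devs[i], devs[j]),
        ref$plasmid, ref$cassette))
    }
  }
  out
}

#' @rdname check_crosstalk
#' @export
check_sigma54_proximity <- function(design) {
  stopifnot(inherits(design, "circuit_design"))
  out <- no_violations()
  for (pid in vapply(design$plasmids, `[[`, "", "id")) {
    seen_upstream <- FALSE
    for (k in seq_along(design$cassettes)) {
      cs <- design$cassettes[[k]]
      if (cs$plasmid != pid) next
      for (pr in cs$promoters) {
        if (pr$sigma_class != "sigma54") next
        if (seen_upstream) {
          out <- rbind(out, violation(
            "sigma54_proximity", "error",
            sprintf("sigma-54 promoter %s lies downstream of another sigma-54 promoter on plasmid %s and can be activated constitutively by supercoiling; insulate the modules on separate plasmids.",
                    pr$name, pid),
            pid, k))
        }
        seen_upstream <- TRUE
      }
    }
  }
  out
}

#' @rdname check_crosstalk
#' @export
check_tandem_interference <- function(design) {
  stopifnot(inherits(design, "circuit_design"))
  out <- no_violations()
  for (k in seq_along(design$cassettes)) {
    cs <- design$cassettes[[k]]
    if (length(cs$promoters) < 2L) next
    for (idx in seq(2L, length(cs$promoters))) {
      pr <- cs$promoters[[idx]]
      if (isTRUE(pr$regulator_dual_function)) {
        out <- rbind(out, violation(
          "tandem_dual_function_downstream", "error",
          sprintf("promoter %s with dual-function regulator %s sits downstream in a tandem pair; unliganded regulator binding loops the promoter and silences the transcript. Place it upstream or use separate cassettes.",
                  pr$name, if (is.null(pr$regulator)) "?" else pr$regulator),
          cs$plasmid, k))
      }
    }
  }
  out
}

#' @rdname check_crosstalk
#' @export
check_operator_repeats <- function(design) {
  stopifnot(inherits(design, "circuit_design"))
  out <- no_violations()
  for (k in seq_along(design$cassettes)) {
    cs <- design$cassettes[[k]]
    ids <- character(); arm <- integer()
    for (p_idx in seq_along(cs$promoters)) {
      for (site in cs$promoters[[p_idx]]$operator_sites) {
        ids <- c(ids, site$identity); arm <- c(arm, p_idx)
      }
    }
    if (!length(ids)) next
    for (ident in unique(ids)) {
      n <- sum(ids == ident)
      arms <- unique(arm[ids == ident])
      if (n >= 4L) {
        out <- rbind(out, violation(
          "operator_repeat_4x", "error",
          sprintf("%d identical %s operator sites in one transcript: accumulated 5'-UTR hairpins will block expression in every condition.",
                  n, ident),
          cs$plasmid, k))
      } else if (n == 2L && length(arms) > 1L) {
        out <- rbind(out, violation(
          "operator_tandem_repeat", "warning",
          sprintf("identical %s operator sites repeated across both arms of a tandem transcript: pronounced 5'-UTR structure will skew the upstream arm; use discrete expression cassettes.",
                  ident),
          cs$plasmid, k))
      } else if (n == 1L) {
        out <- rbind(out, violation(
          "operator_single_site", "warning",
          sprintf("a single %s operator site cannot fully repress the transcript; add a second site of perfect dyad symmetry.",
                  ident),
          cs$plasmid, k))
      }
    }
  }
  out
}

#' @rdname check_crosstalk
#' @param devices Named list of [input_device()]s keyed by promoter name
#'   (used to evaluate maximal outputs).
#' @param max_ratio Tolerated fold-imbalance between sub-module maxima.
#' @param not_gate_alpha_max Maximal advisable RBS factor on a repressed
#'   output stage.
#' @export
check_rbs_balance <- function(design, devices = NULL, max_ratio = 5,
                              not_gate_alpha_max = 0.5) {
  stopifnot(inherits(design, "circuit_design"))
  out <- no_violations()

  # NOT-stage leak risk: repressed transcript with a strong RBS
  for (k in seq_along(design$cassettes)) {
    cs <- design$cassettes[[k]]
    n_sites <- sum(vapply(cs$promoters,
                          function(pr) length(pr$operator_sites), 0L))
    if (n_sites > 0L && cs$rbs$alpha > not_gate_alpha_max) {
      out <- rbind(out, violation(
        "not_gate_strong_rbs", "warning",
        sprintf("repressed output stage (cds %s) uses a strong RBS (alpha = %.2g > %.2g): expression leak in the OFF state; attenuate with a weaker RBS.",
                cs$cds, cs$rbs$alpha, not_gate_alpha_max),
        cs$plasmid, k))
    }
  }

  if (is.null(devices)) return(out)

  # maximal output alpha*(A+B) per device-driven module, grouped by cds
  mods <- list()
  for (k in seq_along(design$cassettes)) {
    cs <- design$cassettes[[k]]
    for (pr in cs$promoters) {
      if (is.null(pr$inducer) || is.na(pr$inducer)) next
      dev <- devices[[pr$name]]
      if (is.null(dev))
        stop("configuration error: no device parameters supplied for input promoter '",
             pr$name, "'.", call. = FALSE)
      eff <- effective_hill(dev)
      # the two HrpRS activator arms feed one AND gate even though their
      # coding sequences differ
      gate_key <- if (tolower(cs$cds) %in% c("hrps", "hrpr")) "HrpRS AND"
        else cs$cds
      mods[[length(mods) + 1L]] <- list(
        gate = gate_key, ymax = cs$rbs$alpha * (eff$A + eff$B),
        plasmid = cs$plasmid, cassette = k, promoter = pr$name)
    }
  }
  by_gate <- split(mods, vapply(mods, `[[`, "", "gate"))
  for (grp in by_gate) {
    if (length(grp) < 2L) next
    ymax <- vapply(grp, `[[`, 0, "ymax")
    ratio <- max(ymax) / min(ymax)
    if (ratio > max_ratio) {
      worst <- grp[[which.min(ymax)]]
      out <- rbind(out, violation(
        "rbs_imbalance", "warning",
        sprintf("sub-modules feeding the %s gate stage are stoichiometrically mismatched (maximal outputs differ %.1f-fold > %.1f-fold): rebalance RBS strengths.",
                worst$gate, ratio, max_ratio),
        worst$plasmid, worst$cassette))
    }
  }
  out
}

#' Run all design-rule checks
#'
#' Aggregates every check over a circuit design. The report is a pure,
#' deterministic function of the design: violations are ordered by
#' (plasmid, cassette, rule_id).
#'
#' @param design A [circuit_design()].
#' @param devices Optional named list of [input_device()]s for the
#'   stoichiometric-balance check.
#' @param ... Passed to [check_rbs_balance()].
#' @return A data.frame of class `drc_report`; attribute `has_errors` is
#'   `TRUE` iff any violation has severity `"error"`.
#' @export
run_drc <- function(design, devices = NULL, ...) {
  stopifnot(inherits(design, "circuit_design"))
  rep <- rbind(check_crosstalk(design),
               check_sigma54_proximity(design),
               check_tandem_interference(design),
               check_operator_repeats(design),
               check_rbs_balance(design, devices, ...))
  rep <- rep[order(rep$plasmid, rep$cassette, rep$rule_id), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, has_errors = any(rep$severity == "error"),
            class = c("drc_report", "data.frame"))
}

#' @export
print.drc_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("DRC: no violations.\n")
    return(invisible(x))
  }
  cat(sprintf("DRC: %d violation(s), %d error(s)\n", nrow(x),
              sum(x$severity == "error")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %s (plasmid %s, cassette %d): %s\n",
                toupper(x$severity[i]), x$rule_id[i], x$plasmid[i],
                x$cassette[i], x$message[i]))
  invisible(x)
}

#' Failure-mode coverage table
#'
#' Maps each documented failure mode of layered circuit engineering to the
#' check that audits it, for coverage auditing.
#'
#' @return data.frame with columns `device`, `failure_mode`, `check`.
#' @export
drc_rule_table <- function() {
  data.frame(
    device = c("input switches", "AND gate", "AND gate", "OR gate",
               "OR gate", "NIMPLY (OR-NOT)", "NIMPLY (OR-NOT)", "XOR",
               "XOR"),
    failure_mode = c(
      "genetic crosstalk between input switch devices",
      "stoichiometric mismatch of AND-gate activators (leaky AND gate)",
      "sigma-54 promoter switched on by upstream sigma-54 supercoiling",
      "stoichiometric mismatch of OR-gate arms (skewed OR gate)",
      "tandem-promoter transcription interference (dual-function regulator downstream)",
      "insufficient repression from a single operator site",
      "translation interference from operator-site 5'-UTR structure",
      "insufficient repressor level for distal operator sites",
      "repeated operator sites across tandem arms (5'-UTR interference)"),
    check = c("check_crosstalk", "check_rbs_balance",
              "check_sigma54_proximity", "check_rbs_balance",
              "check_tandem_interference", "check_operator_repeats",
              "check_operator_repeats", "check_rbs_balance",
              "check_operator_repeats"),
    stringsAsFactors = FALSE)
}

#' Read / write circuit designs as JSON
#'
#' @param design A [circuit_design()].
#' @param path JSON file path.
#' @return `read_circuit_json` returns a [circuit_design()].
#' @export
write_circuit_json <- function(design, path) {
  stopifnot(inherits(design, "circuit_design"))
  obj <- list(schema_version = 1L, plasmids = design$plasmids,
              cassettes = design$cassettes,
              orthogonality_evidence = design$orthogonality_evidence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_circuit_json
#' @export
read_circuit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$plasmids) || is.null(obj$cassettes))
    stop("circuit JSON must contain 'plasmids' and 'cassettes'.",
         call. = FALSE)
  ev <- obj$orthogonality_evidence
  circuit_design(obj$plasmids, obj$cassettes,
                 if (is.null(ev)) list() else ev)
}
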