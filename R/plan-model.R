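#' Delivery machine model
#'
#' Geometry of the treatment machine as seen at the isocenter plane:
#' source-axis distance and the MLC leaf-pair band boundaries along the
#' y axis of the beam's-eye view (aligned with patient z for a coplanar arc
#' at collimator 0).
#'
#' @param sad source-axis distance in mm (> 0).
#' @param leaf_pair_boundaries strictly increasing numeric vector of N+1 band
#'   edges at the isocenter plane, mm, for N leaf pairs. The default is 40
#'   pairs of 5 mm leaves spanning -100..100 mm.
#' @param max_leaf_position maximum leaf tip excursion from the central axis,
#'   mm.
#' @param jaw_limits length-2 jaw travel limits, mm.
#' @return A `machine_model` object.
#' @export
machine_model <- function(sad = 1000,
                          leaf_pair_boundaries = seq(-100, 100, by = 5),
                          max_leaf_position = 200,
                          jaw_limits = c(-200, 200)) {
  b <- as.numeric(leaf_pair_boundaries)
  if (length(b) < 2L || any(diff(b) <= 0)) {
    arc_input_error("machine_model: leaf_pair_boundaries must be strictly increasing with >= 2 entries")
  }
  if (!is.numeric(sad) || sad <= 0) arc_input_error("machine_model: sad must be > 0")
  structure(list(sad = as.numeric(sad),
                 leaf_pair_boundaries = b,
                 n_pairs = length(b) - 1L,
                 max_leaf_position = as.numeric(max_leaf_position),
                 jaw_limits = as.numeric(jaw_limits)),
            class = "machine_model")
}

#' @export
print.machine_model <- function(x, ...) {
  cat(sprintf("<machine_model> SAD %g mm, %d leaf pairs spanning [%g, %g] mm\n",
              x$sad, x$n_pairs, min(x$leaf_pair_boundaries), max(x$leaf_pair_boundaries)))
  invisible(x)
}

machines_compatible <- function(a, b) {
  isTRUE(all.equal(a$sad, b$sad)) &&
    length(a$leaf_pair_boundaries) == length(b$leaf_pair_boundaries) &&
    isTRUE(all.equal(a$leaf_pair_boundaries, b$leaf_pair_boundaries))
}

#' Prescription specification
#'
#' @param dose_per_fraction dose per fraction in Gy.
#' @param n_fractions number of fractions.
#' @param idl_percent prescription isodose line in percent, `(0, 100]`. An
#'   IDL below 100 prescribes to a lower isodose surface, implying a hotter
#'   maximum inside the target (see [idl_to_max_percent()]).
#' @return A `prescription_spec` object.
#' @export
prescription_spec <- function(dose_per_fraction, n_fractions, idl_percent = 100) {
  if (dose_per_fraction <= 0 || n_fractions <= 0) {
    arc_input_error("prescription_spec: doses and fraction count must be positive")
  }
  if (idl_percent <= 0 || idl_percent > 100) {
    arc_input_error("prescription_spec: idl_percent must be in (0, 100]")
  }
  structure(list(dose_per_fraction = as.numeric(dose_per_fraction),
                 n_fractions = as.integer(n_fractions),
                 idl_percent = as.numeric(idl_percent)),
            class = "prescription_spec")
}

#' Total prescribed dose in Gy
#' @param rx a [prescription_spec()].
#' @export
rx_total_gy <- function(rx) rx$dose_per_fraction * rx$n_fractions

#' Arc plan container
#'
#' An arc as an ordered list of control points: gantry angle, per-leaf-pair
#' bank positions at the isocenter plane and cumulative meterset weight, plus
#' the machine model and total monitor units. Bank A is the bank on the
#' negative-x side of the beam's-eye view; for every pair
#' `bank_a[i] <= bank_b[i]` (a pair with equal tips is closed).
#'
#' @param machine a [machine_model()].
#' @param gantry_angle numeric vector of control-point gantry angles in
#'   degrees (IEC 61217); stored modulo 360 in `[0, 360)`.
#' @param bank_a,bank_b numeric matrices `n_cp x n_pairs` of leaf tip
#'   positions at the isocenter plane, mm.
#' @param cum_weight cumulative meterset weights, non-decreasing from 0 to 1.
#' @param total_mu total monitor units of the beam.
#' @param prescription optional [prescription_spec()].
#' @return An `arc_plan` object.
#' @export
arc_plan <- function(machine, gantry_angle, bank_a, bank_b, cum_weight,
                     total_mu, prescription = NULL) {
  if (!inherits(machine, "machine_model")) arc_input_error("arc_plan: machine must be a machine_model")
  n <- length(gantry_angle)
  if (n < 2L) arc_malformed_plan("arc_plan: a plan needs at least 2 control points")
  bank_a <- as.matrix(bank_a)
  bank_b <- as.matrix(bank_b)
  if (!identical(dim(bank_a), dim(bank_b)) || nrow(bank_a) != n ||
      ncol(bank_a) != machine$n_pairs) {
    arc_malformed_plan("arc_plan: bank matrices must be n_control_points x n_pairs")
  }
  if (any(bank_a > bank_b + 1e-6)) {
    arc_malformed_plan("arc_plan: bank_a must not exceed bank_b for any leaf pair")
  }
  w <- as.numeric(cum_weight)
  if (length(w) != n) arc_malformed_plan("arc_plan: cum_weight length must match control points")
  if (any(diff(w) < -1e-9)) arc_malformed_plan("arc_plan: cumulative meterset weights must be non-decreasing")
  if (abs(w[1]) > 1e-6 || abs(w[n] - 1) > 1e-6) {
    arc_malformed_plan("arc_plan: cumulative meterset weights must start at 0 and end at 1")
  }
  w[1] <- 0; w[n] <- 1
  if (!is.numeric(total_mu) || total_mu <= 0) arc_malformed_plan("arc_plan: total_mu must be positive")
  if (!is.null(prescription) && !inherits(prescription, "prescription_spec")) {
    arc_input_error("arc_plan: prescription must be a prescription_spec or NULL")
  }
  structure(list(machine = machine,
                 gantry_angle = as.numeric(gantry_angle) %% 360,
                 bank_a = bank_a, bank_b = bank_b,
                 cum_weight = w,
                 total_mu = as.numeric(total_mu),
                 prescription = prescription),
            class = "arc_plan")
}

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf("<arc_plan> %d control points, %d leaf pairs, %.2f MU\n",
              length(x$gantry_angle), x$machine$n_pairs, x$total_mu))
  invisible(x)
}

n_control_points <- function(plan) length(plan$gantry_angle)

#' Per-segment monitor units
#'
#' MU of the segment between consecutive control points, attributed to the
#' starting control point (start-of-segment convention); length is one less
#' than the number of control points and the values sum to `total_mu`.
#'
#' @param plan an [arc_plan()].
#' @export
segment_mu <- function(plan) diff(plan$cum_weight) * plan$total_mu

#' Monitor-unit reduction percentage
#'
#' `100 * (mu_ref - mu_new) / mu_ref`, rounded to one decimal — the headline
#' bookkeeping figure when comparing an MU-limited replan against its parent
#' plan.
#'
#' @param mu_ref reference (parent plan) MU, > 0.
#' @param mu_new MU of the replanned beam.
#' @return Reduction in percent, one decimal.
#' @examples
#' mu_reduction_percent(5200.55, 4937.07)  # 5.1
#' @export
mu_reduction_percent <- function(mu_ref, mu_new) {
  if (any(mu_ref <= 0)) arc_domain_error("mu_reduction_percent: mu_ref must be > 0")
  round(100 * (mu_ref - mu_new) / mu_ref, 1)
}

#' Number of control points in an evenly spaced arc
#'
#' @param arc_span_deg arc span in degrees.
#' @param spacing_deg gantry spacing in degrees; must divide the span.
#' @return `span / spacing + 1` control points (e.g. a full 360-degree arc at
#'   3-degree spacing has 121).
#' @export
arc_control_point_count <- function(arc_span_deg, spacing_deg) {
  if (spacing_deg <= 0 || arc_span_deg <= 0) {
    arc_domain_error("arc_control_point_count: span and spacing must be positive")
  }
  k <- arc_span_deg / spacing_deg
  if (abs(k - round(k)) > 1e-9) {
    arc_domain_error("arc_control_point_count: spacing must divide the arc span")
  }
  as.integer(round(k)) + 1L
}

# ---- plan text dialect -----------------------------------------------------

#' Write / read an arc plan in the versioned plain-text dialect
#'
#' The `ARCPLAN 1` dialect is line-oriented: a machine header (SAD, leaf
#' boundaries, limits), total MU, optional prescription, then one `cp` line
#' per control point (gantry angle to 0.01 degree, cumulative weight) followed
#' by `a` and `b` lines with bank positions to 0.01 mm. Reading a file written
#' by this function reproduces the plan exactly at that stated precision, and
#' write-read-write is byte-stable.
#'
#' @param plan an [arc_plan()].
#' @param path file path; `.gz` enables gzip compression.
#' @return `write_plan_text()` returns `path` invisibly; `read_plan_text()`
#'   returns the [arc_plan()]. An unknown version line raises an explicit
#'   format error.
#' @export
write_plan_text <- function(plan, path) {
  n <- n_control_points(plan)
  if (n < 2L) arc_malformed_plan("write_plan_text: refusing to write a plan with < 2 control points")
  fmt2 <- function(x) sprintf("%.2f", x)
  header <- c(
    "ARCPLAN 1",
    paste("sad", fmt2(plan$machine$sad)),
    paste("boundaries", paste(fmt2(plan$machine$leaf_pair_boundaries), collapse = " ")),
    paste("max_leaf_position", fmt2(plan$machine$max_leaf_position)),
    paste("jaw_limits", paste(fmt2(plan$machine$jaw_limits), collapse = " ")),
    paste("total_mu", sprintf("%.4f", plan$total_mu))
  )
  if (!is.null(plan$prescription)) {
    header <- c(header, paste("prescription",
                              sprintf("%.4f", plan$prescription$dose_per_fraction),
                              plan$prescription$n_fractions,
                              sprintf("%.2f", plan$prescription$idl_percent)))
  }
  header <- c(header, paste("n_control_points", n))
  body <- character(3L * n)
  for (i in seq_len(n)) {
    body[3 * i - 2] <- paste("cp", fmt2(plan$gantry_angle[i]),
                             sprintf("%.6f", plan$cum_weight[i]))
    body[3 * i - 1] <- paste("a", paste(fmt2(plan$bank_a[i, ]), collapse = " "))
    body[3 * i]     <- paste("b", paste(fmt2(plan$bank_b[i, ]), collapse = " "))
  }
  con <- open_text(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @rdname write_plan_text
#' @export
read_plan_text <- function(path) {
  con <- open_text(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1L || lines[1] != "ARCPLAN 1") {
    arc_format_error(sprintf("'%s' is not an ARCPLAN version-1 plan file", path))
  }
  is_cp <- startsWith(lines, "cp ")
  first_cp <- which(is_cp)[1]
  kv <- read_kv_lines(lines[2:(first_cp - 1)])
  machine <- machine_model(sad = num_field(kv, "sad"),
                           leaf_pair_boundaries = num_field(kv, "boundaries"),
                           max_leaf_position = num_field(kv, "max_leaf_position"),
                           jaw_limits = num_field(kv, "jaw_limits"))
  rx <- NULL
  if (!is.null(kv[["prescription"]])) {
    pv <- num_field(kv, "prescription")
    rx <- prescription_spec(pv[1], pv[2], pv[3])
  }
  n <- as.integer(num_field(kv, "n_control_points"))
  cps <- lines[first_cp:length(lines)]
  if (length(cps) != 3L * n) arc_format_error("plan file control-point block has unexpected length")
  ang <- numeric(n); w <- numeric(n)
  np <- machine$n_pairs
  bank_a <- matrix(0, n, np); bank_b <- matrix(0, n, np)
  for (i in seq_len(n)) {
    cpv <- num_field(read_kv_lines(cps[3 * i - 2]), "cp")
    ang[i] <- cpv[1]; w[i] <- cpv[2]
    bank_a[i, ] <- num_field(read_kv_lines(cps[3 * i - 1]), "a")
    bank_b[i, ] <- num_field(read_kv_lines(cps[3 * i]), "b")
  }
  arc_plan(machine, ang, bank_a, bank_b, w, num_field(kv, "total_mu"), rx)
}

#' Read a plan from any supported format
#'
#' Dispatches on file extension: `.dcm` goes to [read_rtplan()], everything
#' else to [read_plan_text()].
#'
#' @param path plan file path.
#' @param ... passed to the format reader.
#' @export
read_plan <- function(path, ...) {
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) read_rtplan(path, ...) else read_plan_text(path)
}
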