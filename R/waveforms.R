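#' Sampled RF pulse shapes
#'
#' An `rf_shape` is a tibble with one row per waveform sample and columns
#' `time` (s, sample midpoints), `amplitude` (rad/s, always >= 0) and `phase`
#' (rad, unwrapped), together with attributes `duration` (s), `dt` (s,
#' uniform dwell), `peak_amplitude` (rad/s) and `label`. Frequency-modulated
#' pulses are stored in amplitude/phase form; the frequency offset of a shape
#' is recovered by [shape_offsets()] under the midpoint finite-difference
#' convention used throughout (see Details).
#'
#' @details The phase track is the midpoint cumulative integral of the
#' frequency offset: `phase[i] = sum(offset[1:(i-1)]) * dt + offset[i] * dt/2`.
#' [shape_offsets()] inverts this recursion exactly, so the
#' (amplitude, phase) and (amplitude, offset) representations interconvert
#' losslessly.
#'
#' @param time,amplitude,phase equal-length numeric vectors of sample
#'   midpoints (s), amplitudes (rad/s) and phases (rad).
#' @param dt sample dwell time (s).
#' @param peak_amplitude nominal peak amplitude (rad/s); defaults to the
#'   maximum sampled amplitude.
#' @param label short text label carried through to shape files.
#' @return A tibble of class `rf_shape`.
#' @export
rf_shape <- function(time, amplitude, phase, dt,
                     peak_amplitude = max(amplitude), label = "shape") {
  if (length(time) == 0L) stop("rf_shape: shape must contain at least one sample")
  if (any(amplitude < 0)) stop("rf_shape: amplitude must be non-negative")
  if (max(amplitude) > peak_amplitude * (1 + 1e-9))
    stop("rf_shape: sampled amplitude exceeds peak_amplitude")
  out <- tibble::tibble(time = time, amplitude = amplitude, phase = phase)
  attr(out, "dt") <- dt
  attr(out, "duration") <- length(time) * dt
  attr(out, "peak_amplitude") <- peak_amplitude
  attr(out, "label") <- label
  class(out) <- c("rf_shape", class(out))
  out
}

#' @rdname rf_shape
#' @param shape an `rf_shape`.
#' @export
shape_offsets <- function(shape) {
  ph <- shape$phase
  dt <- attr(shape, "dt")
  n <- length(ph)
  off <- numeric(n)
  off[1] <- 2 * ph[1] / dt
  if (n > 1) for (i in 2:n) off[i] <- 2 * (ph[i] - ph[i - 1]) / dt - off[i - 1]
  off
}

# midpoint integral of a frequency-offset track, inverse of shape_offsets()
phase_from_offsets <- function(offset, dt) {
  cumsum(offset) * dt - offset * dt / 2
}

#' @export
print.rf_shape <- function(x, ...) {
  cat(sprintf("<rf_shape> %s: %d samples, %.4g ms, peak %.4g Hz\n",
              attr(x, "label"), nrow(x), attr(x, "duration") * 1e3,
              attr(x, "peak_amplitude") / (2 * pi)))
  NextMethod()
}

## ---------------------------------------------------------------------------
## RAFF packets

# one forward sweep element: w1(t) = w1max sin(ws t), dW(t) = w1max cos(ws t)
raff_element <- function(omega1max, ws, Te, ns) {
  dt <- Te / ns
  tm <- (seq_len(ns) - 0.5) * dt
  amp <- omega1max * sin(ws * tm)
  off <- omega1max * cos(ws * tm)
  list(amp = amp, off = off, dt = dt)
}

# assemble the rotary-echo packet P P_pi^-1 P_pi P^-1 from forward element
# samples: elements 2/4 are time-reversed with negated offset, elements 2/3
# carry a pi RF phase shift
assemble_packet <- function(amp, off, ph_extra, dt) {
  ampR <- rev(amp)
  offR <- -rev(off)
  phF <- phase_from_offsets(off, dt) + ph_extra
  phR <- phase_from_offsets(offR, dt) + rev(ph_extra)
  list(amplitude = c(amp, ampR, amp, ampR),
       phase = c(phF, phR + pi, phF + pi, phR),
       dt = dt)
}

new_p_packet <- function(parts, TL, rank, omega1max_hz, element_duration, label) {
  ns <- length(parts$amplitude)
  shape <- rf_shape(time = (seq_len(ns) - 0.5) * parts$dt,
                    amplitude = parts$amplitude, phase = parts$phase,
                    dt = parts$dt,
                    peak_amplitude = max(parts$amplitude), label = label)
  structure(list(
    shape = shape,
    TL = TL, rank = rank,
    omega1max_hz = omega1max_hz,
    omega1max = 2 * pi * omega1max_hz,
    alpha1 = 45,
    alpha2 = atan(TL) * 180 / pi,
    element_duration = element_duration,
    packet_duration = 4 * element_duration,
    n_samples = ns,
    label = label
  ), class = "p_packet")
}

#' Construct a (stretched) RAFF2 rotary-echo packet
#'
#' Builds the four-element packet P P_pi^-1 P_pi P^-1 of a RAFF2 pulse with
#' stretching factor `TL`. The forward element sweeps the effective field with
#' amplitude modulation `w1max*sin(wm t)` and frequency modulation
#' `w1max*cos(wm t)`; at `TL = 1` the sweep rate equals `w1max`, placing the
#' fictitious field of the second rotating frame at a stationary 45 degrees.
#' Elements 2 and 4 are time-reversed with negated frequency offset, and the
#' inner pair carries a pi RF phase shift, forming a rotating-frame rotary
#' echo.
#'
#' The element (refocusing) duration is `TL * pi / (sqrt(2) * 2*pi*nominal_hz)`
#' so that the four-element packet lasts `TL * 4*pi / (sqrt(2) * w1max)`
#' (2.26 ms at the nominal 625 Hz), matching the packet-length and
#' refocusing-length columns of the pulse-parameter presets. Durations are
#' computed from `nominal_hz` rather than `omega1max_hz` because preset tables
#' scale durations from the TL1.0 packet even when the actual peak amplitude
#' differs slightly (e.g. the TL0.6 preset at 608 Hz keeps 1.35 ms).
#'
#' @param omega1max_hz peak RF amplitude in Hz (nominal peak power).
#' @param TL dimensionless stretching factor (> 0); 0.6-2.0 in the presets.
#' @param n_samples total number of waveform samples in the packet
#'   (divisible by 4); 128 by default.
#' @param nominal_hz reference amplitude (Hz) that sets the time base.
#' @return A `p_packet`: a list with the concatenated [rf_shape()] (`$shape`),
#'   the stretching factor, tilt angles `alpha1`/`alpha2` (degrees),
#'   `element_duration` and `packet_duration` (s).
#' @examples
#' pk <- make_raff2_packet(625, TL = 1.0)
#' pk$packet_duration * 1e3  # ~2.26 ms
#' @export
make_raff2_packet <- function(omega1max_hz, TL = 1.0, n_samples = 128,
                              nominal_hz = 625) {
  if (!is.numeric(omega1max_hz) || omega1max_hz <= 0)
    stop("make_raff2_packet: omega1max_hz must be positive")
  if (!is.numeric(TL) || TL <= 0)
    stop("make_raff2_packet: TL must be positive")
  if (n_samples %% 4 != 0)
    stop("make_raff2_packet: n_samples must be divisible by 4")
  w1 <- 2 * pi * omega1max_hz
  Te <- TL * pi / (sqrt(2) * 2 * pi * nominal_hz)
  ws <- (pi / sqrt(2)) / Te   # sweep angle pi/sqrt(2) per element
  ns <- n_samples / 4
  el <- raff_element(w1, ws, Te, ns)
  parts <- assemble_packet(el$amp, el$off, rep(0, ns), el$dt)
  new_p_packet(parts, TL = TL, rank = 2L, omega1max_hz = omega1max_hz,
               element_duration = Te,
               label = sprintf("RAFF2 TL%.1f", TL))
}

#' Construct a RAFFn packet of rank 1-5
#'
#' Rank 2 is exactly [make_raff2_packet()] at `TL = 1`. Rank 1 is a constant
#' amplitude/offset element with the effective field tilted at 45 degrees
#' (`alpha1`). Ranks 3-5 use the fictitious-field recursion in which the field
#' of the highest frame `n` is stationary at 45 degrees with `E_n * Te = pi`:
#' descending frame by frame, `e_{k} = e_{k+1} cos(alpha_{k+1})` and
#' `alpha_k' = e_{k+1} sin(alpha_{k+1})`, down to the first-frame amplitude
#' `w1 = e_1 sin(alpha_1)` and offset `dW = e_1 cos(alpha_1)`. Element
#' durations equal the RAFF2 TL1.0 element so all ranks share the same packet
#' length; peak amplitudes are non-increasing with rank.
#'
#' @param rank integer 1-5, the rotating frame rank n.
#' @inheritParams make_raff2_packet
#' @return A `p_packet`; see [make_raff2_packet()].
#' @export
make_raffn_packet <- function(rank, omega1max_hz = 625, n_samples = 128,
                              nominal_hz = 625) {
  if (!rank %in% 1:5) stop("make_raffn_packet: rank must be an integer in 1..5")
  if (rank == 2L) {
    pk <- make_raff2_packet(omega1max_hz, TL = 1.0, n_samples = n_samples,
                            nominal_hz = nominal_hz)
    pk$rank <- 2L
    pk$label <- "RAFF2"
    attr(pk$shape, "label") <- "RAFF2"
    return(pk)
  }
  w1 <- 2 * pi * omega1max_hz
  Te <- pi / (sqrt(2) * 2 * pi * nominal_hz)
  ns <- n_samples / 4
  if (n_samples %% 4 != 0)
    stop("make_raffn_packet: n_samples must be divisible by 4")
  dt <- Te / ns
  tm <- (seq_len(ns) - 0.5) * dt
  if (rank == 1L) {
    amp <- rep(w1, ns)
    off <- rep(w1, ns)
  } else {
    En <- pi / Te                       # top-frame fictitious field
    e <- rep(En / sqrt(2), ns)          # frame n-1: constant magnitude
    al <- (En / sqrt(2)) * tm           # frame n-1: linear sweep
    for (k in seq_len(rank - 2)) {
      e_new <- e * cos(al)
      al_new <- phase_from_offsets(e * sin(al), dt)
      e <- e_new
      al <- al_new
    }
    amp <- e * sin(al)
    off <- e * cos(al)
  }
  # fold any negative amplitude into a pi phase flip
  ph_extra <- ifelse(amp < 0, pi, 0)
  amp <- abs(amp)
  parts <- assemble_packet(amp, off, ph_extra, dt)
  pk <- new_p_packet(parts, TL = 1.0, rank = as.integer(rank),
                     omega1max_hz = max(amp) / (2 * pi),
                     element_duration = Te,
                     label = sprintf("RAFF%d", rank))
  pk
}

#' @export
print.p_packet <- function(x, ...) {
  cat(sprintf("<p_packet> %s: %d samples, packet %.3f ms (element %.3f ms), peak %.0f Hz, alpha2 %.1f deg\n",
              x$label, x$n_samples, x$packet_duration * 1e3,
              x$element_duration * 1e3, x$omega1max_hz, x$alpha2))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Comparison pulses

#' Construct comparison preparation pulses
#'
#' Standard pulses used alongside RAFFn preparations: continuous-wave
#' spin-lock (`CW_SL`, constant amplitude and zero offset), hard pulse
#' (`HARD`, constant amplitude and zero phase), hyperbolic-secant adiabatic
#' full passages of power 1 and 4 (`HS1`, `HS4`) with a tanh-derived frequency
#' sweep truncated at time-bandwidth product `truncation_R`, and an adiabatic
#' half passage (`AHP`): the first half of an HS1 sweep, ending with the
#' effective field in the transverse plane.
#'
#' @param kind one of `"CW_SL"`, `"AHP"`, `"HS1"`, `"HS4"`, `"HARD"`.
#' @param duration pulse duration (s).
#' @param peak_hz peak RF amplitude (Hz).
#' @param truncation_R time-bandwidth product R for the HS kinds (default 20,
#'   ignored otherwise).
#' @param n_samples number of waveform samples.
#' @return An [rf_shape()].
#' @export
make_comparison_pulse <- function(kind, duration, peak_hz, truncation_R = 20,
                                  n_samples = 256) {
  kind <- match.arg(kind, c("CW_SL", "AHP", "HS1", "HS4", "HARD"))
  if (duration <= 0) stop("make_comparison_pulse: duration must be positive")
  if (peak_hz <= 0) stop("make_comparison_pulse: peak_hz must be positive")
  w1 <- 2 * pi * peak_hz
  dt <- duration / n_samples
  tm <- (seq_len(n_samples) - 0.5) * dt
  beta <- acosh(100)  # 1% amplitude truncation of the sech envelope
  if (kind %in% c("CW_SL", "HARD")) {
    amp <- rep(w1, n_samples)
    ph <- rep(0, n_samples)
  } else if (kind %in% c("HS1", "HS4")) {
    tau <- 2 * tm / duration - 1        # -1..1
    p <- if (kind == "HS1") 1 else 4
    amp <- w1 / cosh(beta * tau^p)
    bw <- truncation_R / duration       # full sweep width, Hz
    if (kind == "HS1") {
      off <- 2 * pi * (bw / 2) * tanh(beta * tau) / tanh(beta)
    } else {
      # sweep proportional to the running integral of the squared envelope
      g <- cumsum((1 / cosh(beta * tau^p))^2)
      g <- g - g[1]
      g <- 2 * g / g[length(g)] - 1
      off <- 2 * pi * (bw / 2) * g
    }
    ph <- phase_from_offsets(off, dt)
  } else { # AHP: first half of HS1, sweep ends on resonance at full amplitude
    tau <- tm / duration - 1            # -1..0
    amp <- w1 / cosh(beta * tau)
    bw <- truncation_R / (2 * duration)
    off <- 2 * pi * bw * tanh(beta * tau) / tanh(beta)
    ph <- phase_from_offsets(off, dt)
  }
  rf_shape(time = tm, amplitude = amp, phase = ph, dt = dt,
           peak_amplitude = w1, label = kind)
}

## ---------------------------------------------------------------------------
## Pulse trains

#' Build a pulse train from repeated packets
#'
#' @param packet a `p_packet` (or any [rf_shape()], repeated whole).
#' @param n_packets number of packet repetitions (>= 0); 0 gives an empty
#'   train of zero duration.
#' @return A `pulse_train`: list with the packet, `n_packets`,
#'   `total_duration` (s) and `boundary_times` (s, `n_packets + 1` values).
#' @examples
#' tr <- build_train(make_raff2_packet(625, 1.0), 32)
#' tr$total_duration * 1e3  # ~72.4 ms
#' @export
build_train <- function(packet, n_packets) {
  if (!is.numeric(n_packets) || n_packets < 0 || n_packets != round(n_packets))
    stop("build_train: n_packets must be a non-negative integer")
  dur <- if (inherits(packet, "p_packet")) packet$packet_duration
         else attr(packet, "duration")
  structure(list(
    packet = packet,
    n_packets = as.integer(n_packets),
    total_duration = n_packets * dur,
    boundary_times = seq(0, n_packets * dur, length.out = n_packets + 1)
  ), class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d packets, %.2f ms total\n",
              x$n_packets, x$total_duration * 1e3))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Presets and shape files

#' RAFF2 stretching-factor presets
#'
#' The packaged pulse-parameter presets for RAFF2 stretching factors
#' TL 0.6-2.0: nominal peak amplitude (Hz) and the packet and refocusing
#' (element) lengths (ms). Read from the bundled tab-separated preset file.
#'
#' @return A tibble with columns `TL`, `peak_hz`, `packet_ms`, `refocus_ms`.
#' @export
raff2_presets <- function() {
  path <- system.file("extdata", "raff2_presets.tsv", package = "raffsim")
  out <- utils::read.delim(path, comment.char = "#")
  tibble::as_tibble(out)
}

#' Write and read RF shape files
#'
#' Two-column plain-text shape files with a `#`-comment header carrying the
#' dwell time, peak amplitude and label. The `"plain"` dialect stores
#' amplitude in rad/s and unwrapped phase in rad (lossless roundtrip); the
#' `"normalized"` dialect stores amplitude as a fraction of peak in `[0, 1]`
#' and phase in degrees wrapped to `[0, 360)`, the common vendor convention
#' (phase roundtrips modulo 360 degrees).
#'
#' @param shape an [rf_shape()].
#' @param path file path to write to / read from.
#' @param dialect `"plain"` or `"normalized"`.
#' @return `export_shape()` returns `path` invisibly; `read_shape()` returns
#'   an [rf_shape()].
#' @export
export_shape <- function(shape, path, dialect = c("plain", "normalized")) {
  dialect <- match.arg(dialect)
  if (!inherits(shape, "rf_shape") || nrow(shape) == 0)
    stop("export_shape: shape must be a non-empty rf_shape")
  peak <- attr(shape, "peak_amplitude")
  hdr <- c(
    "# raffsim RF shape",
    sprintf("# dialect: %s", dialect),
    sprintf("# label: %s", attr(shape, "label")),
    sprintf("# n: %d", nrow(shape)),
    sprintf("# dt_s: %.17g", attr(shape, "dt")),
    sprintf("# duration_s: %.17g", attr(shape, "duration")),
    sprintf("# peak_rad_s: %.17g", peak)
  )
  if (dialect == "plain") {
    body <- sprintf("%.17g %.17g", shape$amplitude, shape$phase)
  } else {
    amp <- shape$amplitude / peak
    ph <- (shape$phase * 180 / pi) %% 360
    body <- sprintf("%.17g %.17g", amp, ph)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' @rdname export_shape
#' @export
read_shape <- function(path) {
  if (!file.exists(path)) stop("read_shape: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(ln) == 0) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  dialect <- get_field("dialect")
  if (is.na(dialect)) stop("read_shape: malformed shape file (no dialect header): ", path)
  dt <- as.numeric(get_field("dt_s"))
  peak <- as.numeric(get_field("peak_rad_s"))
  n <- as.integer(get_field("n"))
  vals <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(vals) != 2))
    stop("read_shape: parse error at line ",
         which(lengths(vals) != 2)[1], " of data block in ", path)
  m <- matrix(as.numeric(unlist(vals)), ncol = 2, byrow = TRUE)
  if (!is.na(n) && nrow(m) != n)
    stop("read_shape: truncated shape file: expected ", n, " samples, found ",
         nrow(m), " in ", path)
  if (dialect == "plain") {
    amp <- m[, 1]; ph <- m[, 2]
  } else {
    amp <- m[, 1] * peak
    ph <- m[, 2] * pi / 180
  }
  rf_shape(time = (seq_len(nrow(m)) - 0.5) * dt, amplitude = amp, phase = ph,
           dt = dt, peak_amplitude = peak, label = get_field("label"))
}
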