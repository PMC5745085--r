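#' Write a trajectory to CSV
#'
#' Serializes a trajectory in I/O units with a comment header ('#' lines)
#' carrying the model kind, the parameters (flat I/O-unit keys), and the
#' solver tolerances. Data columns are exactly
#' `time_hpf,N_nM,V_nM,D_nM` (`V_nM` is written as 0 for cold-start).
#'
#' @param traj A `dimer_trajectory` from [integrate_model()].
#' @param path Output file path.
#' @param digits Decimal places for the data values (default 4);
#'   `NULL` writes full double precision (for oracle comparisons).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, digits = 4) {
  stopifnot(inherits(traj, "dimer_trajectory"))
  hdr <- c(sprintf("# model: %s", traj$model),
           vapply(names(params_to_io_list(traj$params)), function(k) {
             sprintf("# %s: %.17g", k, params_to_io_list(traj$params)[[k]])
           }, character(1)),
           sprintf("# rel_tol: %.17g", traj$rel_tol),
           sprintf("# abs_tol: %.17g", traj$abs_tol))
  fmt <- if (is.null(digits)) {
    function(x) sprintf("%.17g", x)
  } else {
    function(x) sprintf(paste0("%.", digits, "f"), x)
  }
  rows <- paste(fmt(s_to_hpf(traj$times)),
                fmt(M_to_nM(traj$states$N)),
                fmt(M_to_nM(traj$states$V)),
                fmt(M_to_nM(traj$states$D)), sep = ",")
  writeLines(c(hdr, "time_hpf,N_nM,V_nM,D_nM", rows), path)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' Parses the comment header back into a [kinetic_parameters] object and
#' validates the column header and time monotonicity. The conservation
#' ledger integrals are not stored in the CSV, so [mass_ledger()] cannot be
#' applied to a re-read trajectory.
#'
#' @param path File path.
#' @return A `dimer_trajectory` (without cumulative ledger fields).
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- lines[is_hdr]
  body <- lines[!is_hdr]
  if (length(body) < 2 || body[1] != "time_hpf,N_nM,V_nM,D_nM") {
    stop("trajectory CSV header mismatch: expected 'time_hpf,N_nM,V_nM,D_nM'",
         call. = FALSE)
  }
  kv <- sub("^# *", "", meta)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  meta_map <- stats::setNames(as.list(vals), keys)
  model <- match_model_kind(meta_map[["model"]])
  pkeys <- setdiff(keys, c("model", "rel_tol", "abs_tol"))
  params <- params_from_io_list(lapply(meta_map[pkeys], as.numeric))

  df <- utils::read.csv(textConnection(body))
  if (any(diff(df$time_hpf) <= 0)) {
    stop("trajectory CSV times must be strictly increasing", call. = FALSE)
  }
  structure(list(model = model, params = params,
                 times = hpf_to_s(df$time_hpf),
                 states = data.frame(N = nM_to_M(df$N_nM),
                                     V = nM_to_M(df$V_nM),
                                     D = nM_to_M(df$D_nM)),
                 rel_tol = as.numeric(meta_map[["rel_tol"]]),
                 abs_tol = as.numeric(meta_map[["abs_tol"]])),
            class = "dimer_trajectory")
}

#' Write a synthetic dataset to CSV
#'
#' Long format `time_hpf,replicate,value` (value in nM) with a '#'
#' metadata header recording the noise scale, the seed, the model kind, and
#' the generating parameters.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  io <- params_to_io_list(dataset$true_params)
  hdr <- c(sprintf("# model: %s", dataset$model),
           sprintf("# sigma: %.17g", dataset$sigma),
           sprintf("# seed: %d", dataset$seed),
           vapply(names(io), function(k) sprintf("# %s: %.17g", k, io[[k]]),
                  character(1)))
  nrep <- nrow(dataset$observed)
  long <- data.frame(time_hpf = rep(s_to_hpf(dataset$times), each = nrep),
                     replicate = rep(seq_len(nrep), length(dataset$times)),
                     value = as.vector(dataset$observed))
  rows <- sprintf("%.17g,%d,%.17g", long$time_hpf, long$replicate, long$value)
  writeLines(c(hdr, "time_hpf,replicate,value", rows), path)
  invisible(path)
}

#' Read a synthetic dataset CSV written by [write_dataset_csv()]
#'
#' @param path File path.
#' @return A `synthetic_dataset` (the `noiseless` trajectory is recomputed
#'   from the stored parameters).
#' @export
read_dataset_csv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  kv <- sub("^# *", "", lines[is_hdr])
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  meta_map <- stats::setNames(as.list(vals), keys)
  body <- lines[!is_hdr]
  if (length(body) < 2 || body[1] != "time_hpf,replicate,value") {
    stop("dataset CSV header mismatch: expected 'time_hpf,replicate,value'",
         call. = FALSE)
  }
  df <- utils::read.csv(textConnection(body))
  model <- match_model_kind(meta_map[["model"]])
  pkeys <- setdiff(keys, c("model", "sigma", "seed"))
  params <- params_from_io_list(lapply(meta_map[pkeys], as.numeric))
  times_hpf <- sort(unique(df$time_hpf))
  reps <- sort(unique(df$replicate))
  obs <- matrix(NA_real_, length(reps), length(times_hpf))
  obs[cbind(match(df$replicate, reps), match(df$time_hpf, times_hpf))] <-
    df$value
  times_s <- hpf_to_s(times_hpf)
  structure(list(times = times_s, observed = obs,
                 noiseless = noiseless_dimer(model, params, times_s),
                 sigma = as.numeric(meta_map[["sigma"]]),
                 true_params = params,
                 seed = as.integer(meta_map[["seed"]]),
                 model = model),
            class = "synthetic_dataset")
}

#' Comparison plot of the two dimer trajectories
#'
#' Plots the heterodimer (primed, blue) and homodimer (cold-start, red)
#' concentration against time, with dashed vertical markers at the start
#' and end of the Nodal production window. Requires ggplot2.
#'
#' @param report A `comparison_report` from [compare_models()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_comparison requires the ggplot2 package", call. = FALSE)
  }
  df <- rbind(
    data.frame(time_hpf = s_to_hpf(report$primed$times),
               D_nM = M_to_nM(report$primed$states$D),
               model = "primed (Vg1-Nodal heterodimer)"),
    data.frame(time_hpf = s_to_hpf(report$cold$times),
               D_nM = M_to_nM(report$cold$states$D),
               model = "cold-start (Nodal homodimer)"))
  p <- report$primed$params
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_hpf, y = .data$D_nM,
                                   colour = .data$model)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = s_to_hpf(c(p$t_on, p$t_off)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(
      "primed (Vg1-Nodal heterodimer)" = "#2166ac",
      "cold-start (Nodal homodimer)" = "#b2182b")) +
    ggplot2::labs(x = "time (hpf)", y = "dimer concentration (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
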