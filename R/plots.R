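#' Plot a current trace
#'
#' Current against time, or against voltage (`type = "iv"`) for ramp sweeps.
#'
#' @param object A `current_trace`.
#' @param type `"time"` or `"iv"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.current_trace <- function(object, type = c("time", "iv"), ...) {
  type <- match.arg(type)
  if (type == "time") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                         y = .data$current_pA)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (s)", y = "current (pA)")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage_mV,
                                         y = .data$current_pA)) +
      ggplot2::geom_path(linewidth = 0.3) +
      ggplot2::labs(x = "membrane potential (mV)", y = "current (pA)")
  }
}

#' Plot a fraction-remaining curve against voltage
#' @param object A `fraction_remaining` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_remaining <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage_mV,
                                       y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = "membrane potential (mV)",
                  y = "fraction of control current")
}

#' Plot a Hill fit with its data
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  cc <- exp(seq(log(min(object$data$conc_uM)), log(max(object$data$conc_uM)),
                length.out = 100))
  curve <- tibble(conc_uM = cc, y = predict(object, cc))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_uM, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)",
                  y = if (object$kind == "inhibition") {
                    "fraction of control"
                  } else "response")
}

#' Plot a Woodhull fit: log IC50 against membrane potential
#' @param object A `woodhull_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.woodhull_fit <- function(object, ...) {
  rtf <- phys_constants(object$temperature)$RT_F_mV
  vv <- seq(min(object$data$voltage_mV), max(object$data$voltage_mV),
            length.out = 50)
  line <- tibble(voltage_mV = vv,
                 IC50 = object$IC50_0 * exp(-object$delta * vv / rtf))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$voltage_mV,
                                            y = .data$IC50)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "membrane potential (mV)", y = "IC50 (uM)")
}

#' Plot a pore-pulling energy profile
#'
#' Best MC-minimized interaction energy against the axial position of the
#' ligand's central nitrogen, annotated with the prime levels of the
#' pore-facing rings.
#'
#' @param object An `energy_profile` (or a list of them, e.g. both receptor
#'   subtypes, plotted together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.energy_profile <- function(object, ...) {
  df <- mutate(as_tibble(object), model = attr(object, "subtype") %||% "pore")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$E_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(
      sec.axis = ggplot2::sec_axis(~ . / 1.5 - 2, name = "prime level")
    ) +
    ggplot2::labs(x = "position of N1 along the pore axis (A)",
                  y = "interaction energy (kcal/mol)")
}

#' Compare energy profiles of several pore models
#' @param profiles Named list of `energy_profile` objects.
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(profiles) {
  df <- imap(profiles, function(p, nm) mutate(as_tibble(p), model = nm)) |>
    list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$E_total,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position of N1 along the pore axis (A)",
                  y = "interaction energy (kcal/mol)", colour = NULL)
}
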