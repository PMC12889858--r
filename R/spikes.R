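#' Convert spike trains to smoothed firing rates
#'
#' Bins each neuron's spike times, convolves the counts with a Gaussian kernel
#' (truncated at four standard deviations, normalized to unit sum), and
#' divides by the bin width to obtain rates in Hz. Neurons whose mean rate
#' falls below `min_rate` are dropped. Bin `t` (0-based) covers
#' `[t_start + t * bin_width, t_start + (t + 1) * bin_width)`; spikes outside
#' `[t_start, t_end)` are ignored.
#'
#' @param spike_times List with one numeric vector of spike times (seconds)
#'   per neuron; empty vectors are allowed (the neuron is dropped).
#' @param t_start,t_end Window bounds in seconds (`t_end > t_start`).
#' @param bin_width Bin width in seconds (default 10 ms).
#' @param kernel_sd Gaussian kernel standard deviation in seconds
#'   (default 50 ms).
#' @param min_rate Minimum mean rate in Hz for a neuron to be kept
#'   (default 0.1 Hz).
#' @return List with `rates` (kept-neurons x bins matrix, Hz), `kept`
#'   (indices of retained neurons), and `times` (bin centers, seconds).
#' @export
#' @examples
#' st <- list(c(0.1, 0.5, 0.52), numeric(0), seq(0, 0.99, by = 0.05))
#' out <- spikes_to_rates(st, 0, 1, min_rate = 0.5)
#' out$kept
spikes_to_rates <- function(spike_times, t_start, t_end, bin_width = 0.01,
                            kernel_sd = 0.05, min_rate = 0.1) {
  if (!is.list(spike_times)) stop("spike_times must be a list of numeric vectors")
  if (bin_width <= 0 || kernel_sd <= 0) stop("bin_width and kernel_sd must be positive")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  n_bins <- floor((t_end - t_start) / bin_width)
  if (n_bins < 1L) stop("window shorter than one bin")

  radius <- ceiling(4 * kernel_sd / bin_width)
  kernel <- stats::dnorm(seq(-radius, radius) * bin_width, sd = kernel_sd)
  kernel <- kernel / sum(kernel)

  n_neurons <- length(spike_times)
  rates <- matrix(0, n_neurons, n_bins)
  for (n in seq_len(n_neurons)) {
    st <- spike_times[[n]]
    st <- st[st >= t_start & st < t_start + n_bins * bin_width]
    counts <- numeric(n_bins)
    if (length(st) > 0) {
      b <- floor((st - t_start) / bin_width) + 1L
      tb <- tabulate(b, nbins = n_bins)
      smoothed <- stats::convolve(tb, rev(kernel), type = "open")
      counts <- smoothed[(radius + 1L):(radius + n_bins)]
    }
    # FFT-based convolution can leave round-off negatives (~1e-16)
    rates[n, ] <- pmax(counts, 0) / bin_width
  }
  kept <- which(rowMeans(rates) >= min_rate)
  list(rates = rates[kept, , drop = FALSE], kept = kept,
       times = t_start + (seq_len(n_bins) - 0.5) * bin_width)
}
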