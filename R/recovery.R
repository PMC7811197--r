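#' Seeded parameter-recovery experiment on canonical phantoms
#'
#' For each requested variant and replicate, generates the canonical
#' phantom under the given imaging conditions (replicate seeds are
#' `base_seed + replicate index`, so the whole experiment is deterministic
#' given `base_seed`), runs the measurement pipeline on the canonical
#' lines, and collects per-replicate estimates of every ground-truth
#' quantity the variant defines.
#'
#' @param variants character vector of phantom variants.
#' @param n_replicates replicates per variant, >= 1.
#' @param base_seed integer; replicate r of any variant uses seed
#'   `base_seed + r`.
#' @param psf_sigma_nm,tilt_range_deg,snr imaging conditions (see
#'   [canonical_imaging()]); the tilt axis is set per variant.
#' @param min_prominence,min_separation_nm peak-detection settings.
#' @return A `recovery_result` list with `estimates` (long tibble:
#'   `variant`, `replicate`, `seed`, `quantity`, `estimate_nm`, `true_nm`)
#'   and `summary` (per quantity: `true_nm`, `mean_estimate_nm`,
#'   `bias_nm`, `sd_nm`, `rmse_nm`, `mae_nm`, `n_replicates`).
#' @examples
#' \donttest{
#' rec <- run_recovery("loose", n_replicates = 2, base_seed = 1)
#' rec$summary
#' }
#' @export
run_recovery <- function(variants = c("tight", "loose", "width", "fibril"),
                         n_replicates = 20, base_seed = 1L,
                         psf_sigma_nm = 2, tilt_range_deg = 60, snr = 2,
                         min_prominence = 0.1, min_separation_nm = 5) {
  stopifnot(n_replicates >= 1)
  variants <- match.arg(variants, several.ok = TRUE)
  est <- purrr::map_dfr(variants, function(variant) {
    # the imaging operators are linear and, apart from the noise draw,
    # deterministic: filter the rendered signal once per variant, then
    # per replicate filter that seed's noise volume and add it on top --
    # exactly apply_imaging(render, im) by linearity, at one FFT pair per
    # replicate instead of a full re-render
    im0 <- canonical_imaging(variant, psf_sigma_nm, tilt_range_deg, snr = Inf)
    base <- canonical_ribbon_phantom(variant, im0)
    noise_sigma <- if (is.finite(snr) && snr > 0) 1 / snr else 0
    d <- dim(base$grid$data)
    mult <- imaging_multiplier(d, base$grid$voxel_size_nm, im0)
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      seed <- as.integer(base_seed + rep_i)
      ph <- base
      if (noise_sigma > 0) {
        noise <- add_noise(voxel_grid(array(0, d), base$grid$voxel_size_nm),
                           noise_sigma, seed)
        if (!is.null(mult)) noise <- apply_fourier_multiplier(noise, mult)
        ph$grid <- voxel_grid(base$grid$data + noise$data,
                              base$grid$voxel_size_nm)
      }
      vals <- measure_phantom(ph, min_prominence, min_separation_nm)
      tibble::tibble(
        variant = variant,
        replicate = rep_i,
        seed = seed,
        quantity = names(vals),
        estimate_nm = as.numeric(vals),
        true_nm = as.numeric(ph$truth[names(vals)])
      )
    })
  })
  summary <- est |>
    dplyr::group_by(.data$variant, .data$quantity) |>
    dplyr::summarise(
      true_nm = .data$true_nm[1],
      mean_estimate_nm = mean(.data$estimate_nm),
      bias_nm = mean(.data$estimate_nm - .data$true_nm),
      sd_nm = stats::sd(.data$estimate_nm),
      rmse_nm = sqrt(mean((.data$estimate_nm - .data$true_nm)^2)),
      mae_nm = mean(abs(.data$estimate_nm - .data$true_nm)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  structure(list(estimates = est, summary = summary),
            class = "recovery_result")
}

# One replicate's named quantity estimates for a canonical phantom.
measure_phantom <- function(ph, min_prominence = 0.1, min_separation_nm = 5) {
  grid <- ph$grid
  lines <- ph$lines
  switch(ph$variant,
    tight = {
      rb <- measure_ribbon(grid, lines, min_prominence, min_separation_nm)
      bl <- measure_belt(grid, lines, min_prominence, min_separation_nm)
      c(om_to_sheet = rb$om_to_closest_sheet_nm,
        intersheet = mean(rb$intersheet_nm),
        im_to_belt = bl$im_to_belt_nm,
        belt_interlayer = mean(bl$belt_interlayer_nm))
    },
    loose = {
      rb <- measure_ribbon(grid, lines, min_prominence, min_separation_nm)
      c(om_to_sheet = rb$om_to_closest_sheet_nm)
    },
    width = {
      c(sheet_width = measure_width(grid, lines, "sheet_width",
                                    min_prominence, min_separation_nm, NULL),
        belt_width = measure_width(grid, lines, "belt_width",
                                   min_prominence, min_separation_nm, NULL))
    },
    fibril = {
      ln <- lines[lines$role == "fibril", ]
      c(fibril_diameter = estimate_fibril_diameter(
        grid, ln, axis_direction = c(0, 1, 0),
        min_prominence = min_prominence,
        min_separation_nm = min_separation_nm
      ))
    }
  )
}

#' Recovery comparison table
#'
#' One row per morphometric quantity comparing the generator's reference
#' value (the study-condition dimension the phantom is built to, nm), the
#' mean recovered estimate with its SD, and a pass flag against the
#' per-quantity tolerance.
#'
#' @param recovery a `recovery_result` from [run_recovery()].
#' @param tolerances_nm named numeric vector of absolute tolerances keyed
#'   by `"variant.quantity"`; defaults to the package's recovery
#'   tolerances (2 nm for tight spacings, 5 nm for the loose offset, 3 nm
#'   for sheet width, 2 nm for the fibril diameter).
#' @return A tibble: `variant`, `quantity`, `reference_nm`,
#'   `mean_estimate_nm`, `sd_nm`, `tolerance_nm`, `pass`.
#' @export
recovery_table <- function(recovery, tolerances_nm = NULL) {
  stopifnot(inherits(recovery, "recovery_result"))
  defaults <- c(
    "tight.om_to_sheet" = 2, "tight.intersheet" = 2,
    "tight.im_to_belt" = 2, "tight.belt_interlayer" = 2,
    "loose.om_to_sheet" = 5,
    "width.sheet_width" = 3, "width.belt_width" = 3,
    "fibril.fibril_diameter" = 2
  )
  tol <- defaults
  if (!is.null(tolerances_nm)) tol[names(tolerances_nm)] <- tolerances_nm
  recovery$summary |>
    dplyr::mutate(
      key = paste(.data$variant, .data$quantity, sep = "."),
      tolerance_nm = unname(tol[.data$key]),
      pass = abs(.data$mean_estimate_nm - .data$true_nm) <= .data$tolerance_nm
    ) |>
    dplyr::transmute(
      variant = .data$variant,
      quantity = .data$quantity,
      reference_nm = .data$true_nm,
      mean_estimate_nm = .data$mean_estimate_nm,
      sd_nm = .data$sd_nm,
      tolerance_nm = .data$tolerance_nm,
      pass = .data$pass
    )
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result>\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname tidy.ribbon_measurement
#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) x$estimates

#' Glance at a recovery result
#'
#' @param x a `recovery_result`.
#' @param ... unused.
#' @return The per-quantity summary tibble.
#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) x$summary
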