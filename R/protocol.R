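#' Acquisition protocols
#'
#' A protocol is a tibble with one row per acquisition block and columns
#' `b` (s/mm^2), `TE` (ms), `TI` (ms, `NA` for T2-only blocks) and `TR` (ms).
#' Two presets cover the acquisitions this package targets: a nine-point
#' diffusion-T1-T2 protocol spanning three echo times and several inversion
#' times at TR = 5000 ms, and a four-echo diffusion-T2 protocol at
#' TR = 4100 ms. Both use a single strong shell at b = 6000 s/mm^2, where
#' the in vivo signal is dominated by intra-axonal water.
#'
#' @param name Preset name, one of `"t1t2-9pt"` or `"t2-4te"`.
#' @return A protocol tibble.
#' @examples
#' protocol_preset("t1t2-9pt")
#' @export
protocol_preset <- function(name = c("t1t2-9pt", "t2-4te")) {
  name <- match.arg(name)
  prot <- switch(name,
    "t1t2-9pt" = new_protocol(
      b  = rep(6000, 9),
      TE = c(80, 110, 110, 150, 80, 110, 110, 150, 150),
      TI = c(200, 200, 331, 200, 906, 906, 1500, 906, 1500),
      TR = rep(5000, 9),
      name = name
    ),
    "t2-4te" = new_protocol(
      b  = rep(6000, 4),
      TE = c(73, 93, 118, 150),
      TI = NA_real_,
      TR = rep(4100, 4),
      name = name
    )
  )
  prot
}

#' Construct and validate a protocol tibble
#'
#' @param b Diffusion weighting per block, s/mm^2.
#' @param TE Echo time per block, ms.
#' @param TI Inversion time per block, ms; `NA` for T2-only blocks.
#' @param TR Repetition time per block, ms.
#' @param name Optional label stored as the `"protocol_name"` attribute.
#' @return A validated protocol tibble.
#' @export
new_protocol <- function(b, TE, TI = NA_real_, TR, name = NULL) {
  prot <- tibble(b = as.numeric(b), TE = as.numeric(TE),
                 TI = as.numeric(TI), TR = as.numeric(TR))
  validate_protocol(prot)
  attr(prot, "protocol_name") <- name
  prot
}

#' @rdname new_protocol
#' @param prot A protocol tibble.
#' @param require_ti Require every block to carry TI and TR (joint T1-T2
#'   fitting); default checks only per-block consistency.
#' @export
validate_protocol <- function(prot, require_ti = FALSE) {
  needed <- c("b", "TE", "TR")
  if (!all(needed %in% names(prot))) {
    abort("Protocol needs columns b, TE, TR (and optionally TI).")
  }
  if (!"TI" %in% names(prot)) prot$TI <- NA_real_
  if (any(prot$TE <= 0)) abort("All echo times must be positive.")
  if (any(prot$b < 0)) abort("b-values must be nonnegative.")
  has_ti <- !is.na(prot$TI)
  if (any(has_ti & (prot$TI < 0 | prot$TR <= prot$TI))) {
    abort("Blocks with TI need TR > TI >= 0.")
  }
  if (require_ti && !all(has_ti)) {
    abort("Protocol mismatch: joint T1-T2 model needs TI and TR in every block.")
  }
  invisible(prot)
}

#' Read or write a protocol file
#'
#' Protocols are stored as plain-text YAML with a `name` and a `points`
#' list, each point holding `b`, `TE`, `TI` (optional) and `TR` in the
#' units of [new_protocol()].
#'
#' @param path File path.
#' @return `read_protocol()` returns a protocol tibble;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  spec <- yaml::read_yaml(path)
  pts <- purrr::map_dfr(spec$points, function(p) {
    tibble(b = as.numeric(p$b), TE = as.numeric(p$TE),
           TI = as.numeric(p$TI %||% NA), TR = as.numeric(p$TR))
  })
  new_protocol(pts$b, pts$TE, pts$TI, pts$TR, name = spec$name)
}

#' @rdname read_protocol
#' @param prot A protocol tibble.
#' @export
write_protocol <- function(prot, path) {
  validate_protocol(prot)
  pts <- purrr::pmap(prot[, c("b", "TE", "TI", "TR")], function(b, TE, TI, TR) {
    p <- list(b = b, TE = TE, TR = TR)
    if (!is.na(TI)) p$TI <- TI
    p
  })
  yaml::write_yaml(list(name = attr(prot, "protocol_name") %||% "custom",
                        points = pts), path)
  invisible(path)
}
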