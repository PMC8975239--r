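#' Pressure unit conversion between cmH2O and mmHg
#'
#' Blood-side pressures are carried in mmHg, airway/pleural pressures in
#' cmH2O. All conversions in the package go through this one constant,
#' 1 mmHg = 1.35951 cmH2O.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
cmh2o_to_mmhg <- function(x) x / 1.35951

#' @rdname cmh2o_to_mmhg
#' @export
mmhg_to_cmh2o <- function(x) x * 1.35951
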