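#' @rdname Slow5Header-class
#' @export
setGeneric("slow5Version", function(x) standardGeneric("slow5Version"))
#' @rdname Slow5Header-class
#' @export
setGeneric("numReadGroups", function(x) standardGeneric("numReadGroups"))
#' @rdname Slow5Header-class
#' @export
setGeneric("headerAttributes", function(x) standardGeneric("headerAttributes"))
#' @rdname Slow5Header-class
#' @export
setGeneric("auxSchema", function(x) standardGeneric("auxSchema"))

#' @rdname Slow5Record-class
#' @export
setGeneric("readID", function(x) standardGeneric("readID"))
#' @rdname Slow5Record-class
#' @export
setGeneric("readGroup", function(x) standardGeneric("readGroup"))
#' @rdname Slow5Record-class
#' @export
setGeneric("digitisation", function(x) standardGeneric("digitisation"))
#' @rdname Slow5Record-class
#' @export
setGeneric("adcOffset", function(x) standardGeneric("adcOffset"))
#' @rdname Slow5Record-class
#' @export
setGeneric("adcRange", function(x) standardGeneric("adcRange"))
#' @rdname Slow5Record-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname Slow5Record-class
#' @export
setGeneric("lenRawSignal", function(x) standardGeneric("lenRawSignal"))
#' @rdname Slow5Record-class
#' @export
setGeneric("rawSignal", function(x) standardGeneric("rawSignal"))
#' @rdname Slow5Record-class
#' @export
setGeneric("auxValues", function(x) standardGeneric("auxValues"))

#' @rdname Slow5Set-class
#' @export
setGeneric("slow5Header", function(x) standardGeneric("slow5Header"))
#' @rdname Slow5Set-class
#' @export
setGeneric("slow5Records", function(x) standardGeneric("slow5Records"))

#' Convert raw ADC signal to picoamperes
#'
#' Applies the standard calibration `(raw + offset) * range / digitisation`
#' element-wise to a record's raw signal.
#'
#' @param x a [Slow5Record-class].
#' @return numeric vector of picoampere values, same length as the signal.
#' @examples
#' r <- Slow5Record(readID = "r1", digitisation = 8192, offset = 6,
#'                  range = 1467.6, samplingRate = 4000, signal = 498L)
#' toPicoamps(r)
#' @export
setGeneric("toPicoamps", function(x) standardGeneric("toPicoamps"))
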