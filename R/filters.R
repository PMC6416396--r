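# Orthogonal wavelet filter banks (Daubechies, symlet, coiflet), standard
# extremal-phase / least-asymmetric coefficient tables. `dec_lo`/`dec_hi`
# are the analysis filters; synthesis uses the transposed transform.

.wavelet_filters <- list(
  db2 = list(
    dec_lo = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
               0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.8365163037378079, -0.2241438680420134,
               -0.12940952255126037)),
  db4 = list(
    dec_lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
               -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
               0.7148465705529157, 0.2303778133088965),
    dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
               -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
               -0.0328830116668852, -0.010597401785069032)),
  db8 = list(
    dec_lo = c(-0.00011747678412476953, 0.0006754494064505693,
               -0.00039174037337694705, -0.004870352993451574,
               0.008746094047405777, 0.013981027917398282,
               -0.044088253930794755, -0.017369301001807547,
               0.12874742662047847, 0.0004724845739132828,
               -0.2840155429615469, -0.015829105256349306,
               0.5853546836542067, 0.6756307362972898,
               0.31287159091429995, 0.05441584224310401),
    dec_hi = c(-0.05441584224310401, 0.31287159091429995, -0.6756307362972898,
               0.5853546836542067, 0.015829105256349306, -0.2840155429615469,
               -0.0004724845739132828, 0.12874742662047847, 0.017369301001807547,
               -0.044088253930794755, -0.013981027917398282, 0.008746094047405777,
               0.004870352993451574, -0.00039174037337694705,
               -0.0006754494064505693, -0.00011747678412476953)),
  sym4 = list(
    dec_lo = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
               0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
               -0.012603967262037833, 0.0322231006040427),
    dec_hi = c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
               0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
               0.02963552764599851, -0.07576571478927333)),
  sym8 = list(
    dec_lo = c(-0.0033824159510061256, -0.0005421323317911481,
               0.03169508781149298, 0.007607487324917605, -0.1432942383508097,
               -0.061273359067658524, 0.4813596512583722, 0.7771857517005235,
               0.3644418948353314, -0.05194583810770904, -0.027219029917056003,
               0.049137179673607506, 0.003808752013890615, -0.01495225833704823,
               -0.0003029205147213668, 0.0018899503327594609),
    dec_hi = c(-0.0018899503327594609, -0.0003029205147213668,
               0.01495225833704823, 0.003808752013890615, -0.049137179673607506,
               -0.027219029917056003, 0.05194583810770904, 0.3644418948353314,
               -0.7771857517005235, 0.4813596512583722, 0.061273359067658524,
               -0.1432942383508097, -0.007607487324917605, 0.03169508781149298,
               0.0005421323317911481, -0.0033824159510061256)),
  coif4 = list(
    dec_lo = c(-1.7849909144933469e-06, -3.259647940030751e-06,
               3.1229861599195265e-05, 6.233885431278719e-05,
               -0.0002599743371222568, -0.0005890202246332165,
               0.0012665610789256603, 0.0037514346971460866,
               -0.0056582838001308835, -0.015211728187697211,
               0.02508225333794961, 0.03933442260558915, -0.09622042453595264,
               -0.06662747236681717, 0.43438603311435653, 0.7822389344242826,
               0.41530842700068227, -0.05607731960356926, -0.08126671024919373,
               0.02668230466960483, 0.01606894713157503, -0.007346167936268051,
               -0.001629492425226786, 0.000892313902537003),
    dec_hi = c(-0.000892313902537003, -0.001629492425226786,
               0.007346167936268051, 0.01606894713157503, -0.02668230466960483,
               -0.08126671024919373, 0.05607731960356926, 0.41530842700068227,
               -0.7822389344242826, 0.43438603311435653, 0.06662747236681717,
               -0.09622042453595264, -0.03933442260558915, 0.02508225333794961,
               0.015211728187697211, -0.0056582838001308835,
               -0.0037514346971460866, 0.0012665610789256603,
               0.0005890202246332165, -0.0002599743371222568,
               -6.233885431278719e-05, 3.1229861599195265e-05,
               3.259647940030751e-06, -1.7849909144933469e-06))
)

#' Orthogonal wavelet filter pair
#'
#' @param mother One of `"db2"`, `"db4"`, `"db8"`, `"sym4"`, `"sym8"`,
#'   `"coif4"`.
#' @return A list with analysis filters `dec_lo` and `dec_hi`.
#' @export
wavelet_filter <- function(mother = "db4") {
  f <- .wavelet_filters[[mother]]
  if (is.null(f)) {
    stop(sprintf("unknown mother wavelet '%s'; available: %s", mother,
                 paste(names(.wavelet_filters), collapse = ", ")), call. = FALSE)
  }
  f
}
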