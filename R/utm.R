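## Transverse Mercator (UTM) projection on the WGS84 ellipsoid using the
## Karney (2011) exact-series formulation (Krueger series to order n^6).
## Accuracy within a UTM zone is well below 1 mm, far inside the <0.5 m
## contract of the segmentation pipeline.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

## series coefficients in the third flattening n, order 6
.tm_constants <- function() {
  f <- .wgs84$f
  n <- f / (2 - f)
  n2 <- n^2; n3 <- n^3; n4 <- n^4; n5 <- n^5; n6 <- n^6
  A <- .wgs84$a / (1 + n) * (1 + n2 / 4 + n4 / 64 + n6 / 256)
  alpha <- c(
    n / 2 - 2 * n2 / 3 + 5 * n3 / 16 + 41 * n4 / 180 - 127 * n5 / 288 +
      7891 * n6 / 37800,
    13 * n2 / 48 - 3 * n3 / 5 + 557 * n4 / 1440 + 281 * n5 / 630 -
      1983433 * n6 / 1935360,
    61 * n3 / 240 - 103 * n4 / 140 + 15061 * n5 / 26880 +
      167603 * n6 / 181440,
    49561 * n4 / 161280 - 179 * n5 / 168 + 6601661 * n6 / 7257600,
    34729 * n5 / 80640 - 3418889 * n6 / 1995840,
    212378941 * n6 / 319334400
  )
  beta <- c(
    n / 2 - 2 * n2 / 3 + 37 * n3 / 96 - n4 / 360 - 81 * n5 / 512 +
      96199 * n6 / 604800,
    n2 / 48 + n3 / 15 - 437 * n4 / 1440 + 46 * n5 / 105 -
      1118711 * n6 / 3870720,
    17 * n3 / 480 - 37 * n4 / 840 - 209 * n5 / 4480 + 5569 * n6 / 90720,
    4397 * n4 / 161280 - 11 * n5 / 504 - 830251 * n6 / 7257600,
    4583 * n5 / 161280 - 108847 * n6 / 3991680,
    20648693 * n6 / 638668800
  )
  list(n = n, A = A, alpha = alpha, beta = beta,
       e = sqrt(f * (2 - f)), k0 = 0.9996)
}

.utm_zone_cm <- function(zone) (zone - 30.5) * 6 * pi / 180

#' Project geographic coordinates to UTM
#'
#' Forward transverse Mercator projection of WGS84 longitude/latitude to
#' UTM easting/northing (metres). The default zone is 30N (central
#' meridian 3 degrees W), the zone used for Irish Sea survey work.
#'
#' @param lon,lat numeric vectors of decimal degrees (WGS84).
#' @param zone UTM zone number (northern hemisphere).
#' @return A data.frame with columns `x` (easting) and `y` (northing) in
#'   metres.
#' @examples
#' project_to_utm(-3, 54.8)   # on the central meridian: easting 500000
#' @export
project_to_utm <- function(lon, lat, zone = 30) {
  stopifnot(length(lon) == length(lat))
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(lat < -80 | lat > 84))
    stop("latitude outside the UTM validity band (-80, 84)")
  cm <- .utm_zone_cm(zone) * 180 / pi
  if (any(lon < cm - 9 | lon > cm + 9))
    stop(sprintf("longitude outside UTM zone %d band (%g to %g degrees)",
                 zone, cm - 9, cm + 9))
  k <- .tm_constants()
  phi <- lat * pi / 180
  dlam <- lon * pi / 180 - .utm_zone_cm(zone)
  s <- sin(phi)
  ## conformal latitude via tau -> tau'
  t <- sinh(atanh(s) - k$e * atanh(k$e * s))
  xip <- atan2(t, cos(dlam))
  etap <- asinh(sin(dlam) / sqrt(t^2 + cos(dlam)^2))
  xi <- xip
  eta <- etap
  for (j in 1:6) {
    xi <- xi + k$alpha[j] * sin(2 * j * xip) * cosh(2 * j * etap)
    eta <- eta + k$alpha[j] * cos(2 * j * xip) * sinh(2 * j * etap)
  }
  data.frame(x = 500000 + k$k0 * k$A * eta, y = k$k0 * k$A * xi)
}

#' Inverse UTM projection
#'
#' Inverse transverse Mercator: UTM easting/northing (metres, northern
#' hemisphere) back to WGS84 longitude/latitude. Round-trips with
#' [project_to_utm()] to well below 1e-6 degrees.
#'
#' @param x,y numeric vectors of easting/northing in metres.
#' @param zone UTM zone number.
#' @return A data.frame with columns `lon` and `lat` in decimal degrees.
#' @export
utm_to_lonlat <- function(x, y, zone = 30) {
  stopifnot(length(x) == length(y))
  k <- .tm_constants()
  xi <- y / (k$k0 * k$A)
  eta <- (x - 500000) / (k$k0 * k$A)
  xip <- xi
  etap <- eta
  for (j in 1:6) {
    xip <- xip - k$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    etap <- etap - k$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  taup <- sin(xip) / sqrt(sinh(etap)^2 + cos(xip)^2)
  lam <- atan2(sinh(etap), cos(xip))
  ## Newton inversion of tau' = tau*sqrt(1+sigma^2) - sigma*sqrt(1+tau^2)
  e <- k$e
  e2 <- e^2
  tau <- taup / (1 - e2)
  for (it in 1:8) {
    sig <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    f <- tau * sqrt(1 + sig^2) - sig * sqrt(1 + tau^2) - taup
    df <- (sqrt(1 + sig^2) * sqrt(1 + tau^2) - sig * tau) * (1 - e2) *
      sqrt(1 + tau^2) / (1 + (1 - e2) * tau^2)
    tau <- tau - f / df
  }
  data.frame(lon = (lam + .utm_zone_cm(zone)) * 180 / pi,
             lat = atan(tau) * 180 / pi)
}
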