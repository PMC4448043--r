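Package: optomc
Title: Monte Carlo Photon Transport for Micro-LED and Fiber Optogenetic
    Light Delivery
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates light delivery from implantable micro-LED probes and
    optical fibers into scattering brain tissue by Monte Carlo photon
    transport.  Photons are launched from a Lambertian micro-LED disc or an
    NA-bounded fiber aperture and propagated through layered sapphire, saline
    and tissue geometries with Henyey-Greenstein anisotropic scattering,
    Beer-Lambert free-path sampling, Fresnel refraction and total internal
    reflection.  Track-length tallies on a cylindrical grid yield fluence-rate
    maps from which channelrhodopsin activation volumes, penetration depths
    and interface irradiance profiles are derived.  Includes analytic oracles
    (Beer-Lambert transmission, energy balance, a scalar reference engine)
    that validate the transport engine independently of any published figure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
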