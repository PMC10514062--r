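Package: sononav
Title: Acoustic Navigation of Microbubble Swarms in Vascular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and simulates ultrasound-driven navigation of
    self-assembled microbubble swarms through vessel networks. Provides a
    vessel-lattice front-end that skeletonizes angiogram-style images into
    centerline graphs and detects and tracks fluorescent swarms; a
    point-source acoustic field model with inverse-square velocity
    attenuation, skull transmission arithmetic, and depth-pressure
    profiles; a per-vessel response model predicting swarm speed and
    direction from transducer geometry with color-coded vasculature maps;
    a seeded stochastic simulator of swarm formation, growth, merging, and
    upstream transport against Poiseuille flow; a combinatorial
    transducer-activation route planner; and synthetic generators for
    device-preset vessel networks, phantom images, flows, and bubble
    injections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
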