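# restainr

Digital re-staining and perceptual color-map optimization for two-stain
brightfield histology images.

## Why

In Hematoxylin–DAB (H–DAB) immunohistochemistry, the blue counterstain and
brown chromogen hues are dictated by dye chemistry, not by what a human
observer can actually distinguish — the brown-on-blue palette occupies a
small corner of perceivable color space, and part of the measured signal is
perceptually lost. `restainr` treats a two-stain image as the bivariate
dataset it really is: every pixel encodes two stain intensities $(u, v)$
through a fixed *bivariate color map*. The package

* unmixes the stains with an unsupervised, PCA-optimized variant of color
  deconvolution,
* extracts the color map inherent in the image,
* designs perceptually linear replacement maps in CIELAB space,
* re-stains the image pixel by pixel, and
* quantifies the perceptual-contrast gain (CIE76 ΔE) on maps, phantom
  images and synthetic ground-truth images,

with a dichromacy simulator for checking map robustness for observers with
impaired color vision. It is aimed at digital-pathology tool builders and
image-analysis researchers working with IHC (and, generically, any
two-stain brightfield) images.

## The model in brief

Beer–Lambert absorption makes stain mixing linear in optical density,
$\vec{od} = c_h\,\vec h + c_d\,\vec d + c_{res}\,\vec\epsilon$ with
$od_c = -\log_{10}(I_c/255)$. Instead of trusting published H–DAB stain
vectors $\vec h, \vec d$ verbatim, the package fits each image's stain
plane as the span of the top-two right singular vectors of the uncentered
OD pixel matrix (zero stain ⇒ zero OD, so the plane passes through the
origin), projects the reference vectors onto it, and takes the plane
normal as the residual direction — minimizing the deconvolution residual
while preserving the reference hues. Replacement maps are bilinear patches
in CIELAB between four corners (white, black, and two free hues), which
makes them perceptually linear; perceived contrast is Euclidean distance
$\Delta E^*_{ab}$ in CIELAB (sRGB, D65, 2° observer) and contrast change
is reported as the ratio $R = C_1/C_2$.

## Worked example

```r
library(restainr)

# A perceptually linear blue/orange replacement map and its contrast profile
m <- design_map("#006EFF", "#FFAD00")
print(m)
#> Bivariate color map (designed), 24 x 24;  corners #FFFFFF #006EFF #FFAD00 #000000;  8.9% of cells gamut-clipped
contrast_profile(m)
#> Map contrast profile: mean 37.4 +/- 15.9, max 82.6 (Delta-E to center)

# A synthetic H-DAB image with ground truth (stain vectors rotated 5 deg
# away from the reference pair, OD noise SD 0.02)
s <- generate_ihc(ihc_params(seed = 11))
model <- fit_stain_model(s$image)
print(model)
#> Fitted stain model: 65536 pixels, 99.8197% of OD sum-of-squares in the stain plane

conc <- deconvolve(s$image, model$basis)
residual_mse(conc)                                        # optimized basis
#> 0.000397
residual_mse(deconvolve(s$image, reference_basis("ruifrok")))
#> 0.000511                                                # reference basis

# Re-stain to blue/orange and measure the object-to-background gain
src  <- extract_map(s$image, conc)        # inherent map + normalization anchors
res  <- restain_image(s$image, model, m, anchors = src)
mask <- foreground_mask(conc)             # Otsu on the DAB channel
contrast_improvement(s$image, res$image, mask)
#> Object-to-background contrast: 44.2 before, 73.2 after (+65.4%)
```

The profile means: every entry of the blue/orange map is on average 37.4
ΔE away from the map's neutral center (maximum 82.6, at the orange
corner) — versus 22.9 / 51.7 for the standard brown/blue palette — and on
the synthetic image the PCA-optimized basis cuts the unmixing residual by
~20% while re-staining raises foreground-to-background contrast by 65%.

A thin command-line launcher covers the same pipeline
(`system.file("cli", "restainr", package = "restainr")`):

```sh
restainr simulate --seed 11 -o synth.png
restainr restain synth.png restained.png --fg "#006EFF" --bg "#FFAD00"
restainr design-map --fg "#006EFF" --bg "#FFAD00" --out map.png
restainr phantom-eval --out matrix.csv
restainr cvd restained.png deutan.png --type deuteranopia
```

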