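{
  "description": "The 15 colors compared pairwise in the phantom evaluation: white, black, gray, the corner hues of five optimized orange-red/blue bivariate color maps, and the standard H-DAB brown/blue. Colors with provenance 'published' are hexadecimal values printed in the study this method derives from; the three map pairs marked 'synthetic stand-in' replace unavailable published hues and were chosen once from the same orange-red/blue hue and lightness families that the published pairs occupy (per the map design rules: at most two basic hues, never red and green together).",
  "colors": [
    { "hex": "#FFFFFF", "role": "control: white",                "provenance": "published" },
    { "hex": "#000000", "role": "control: black",                "provenance": "published" },
    { "hex": "#808080", "role": "control: gray",                 "provenance": "published (value conventional)" },
    { "hex": "#006EFF", "role": "optimized map 1, foreground",   "provenance": "published" },
    { "hex": "#FFAD00", "role": "optimized map 1, background",   "provenance": "published" },
    { "hex": "#FF0000", "role": "optimized map 2, foreground",   "provenance": "published" },
    { "hex": "#0093FF", "role": "optimized map 2, background",   "provenance": "published" },
    { "hex": "#FF6E00", "role": "optimized map 3, foreground",   "provenance": "synthetic stand-in" },
    { "hex": "#0080FF", "role": "optimized map 3, background",   "provenance": "synthetic stand-in" },
    { "hex": "#FF3200", "role": "optimized map 4, foreground",   "provenance": "synthetic stand-in" },
    { "hex": "#3C64FF", "role": "optimized map 4, background",   "provenance": "synthetic stand-in" },
    { "hex": "#FF9600", "role": "optimized map 5, foreground",   "provenance": "synthetic stand-in" },
    { "hex": "#00AAFF", "role": "optimized map 5, background",   "provenance": "synthetic stand-in" },
    { "hex": "#B58C70", "role": "standard H-DAB brown (DAB)",    "provenance": "published" },
    { "hex": "#5C5FA1", "role": "standard H-DAB blue (hematoxylin)", "provenance": "published" }
  ]
}
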