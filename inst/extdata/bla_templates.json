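{
  "anterior": {
    "outline": [
      [0, 0],
      [187, 76.5],
      [340, 255],
      [408, 442],
      [365.5, 807.5],
      [221, 1020],
      [34, 1122],
      [-144.5, 1071],
      [-280.5, 884],
      [-340, 629],
      [-306, 306],
      [-161.5, 119]
    ],
    "la": [
      [0, 0],
      [187, 76.5],
      [340, 255],
      [408, 442],
      [51, 391],
      [-306, 306],
      [-161.5, 119]
    ],
    "ba": [
      [408, 442],
      [365.5, 807.5],
      [221, 1020],
      [34, 1122],
      [-144.5, 1071],
      [-280.5, 884],
      [-340, 629],
      [-306, 306],
      [51, 391]
    ],
    "border": [
      [-306, 306],
      [51, 391],
      [408, 442]
    ],
    "landmarks": [
      [0, 0],
      [340, 255],
      [408, 442],
      [34, 1122],
      [-340, 629],
      [-306, 306]
    ],
    "subregions": {}
  },
  "intermediate": {
    "outline": [
      [0, 0],
      [220, 90],
      [400, 300],
      [480, 600],
      [430, 950],
      [260, 1200],
      [40, 1320],
      [-170, 1260],
      [-330, 1040],
      [-400, 740],
      [-360, 430],
      [-190, 140]
    ],
    "la": [
      [0, 0],
      [220, 90],
      [400, 300],
      [480, 600],
      [60, 535],
      [-360, 430],
      [-190, 140]
    ],
    "ba": [
      [480, 600],
      [430, 950],
      [260, 1200],
      [40, 1320],
      [-170, 1260],
      [-330, 1040],
      [-400, 740],
      [-360, 430],
      [60, 535]
    ],
    "border": [
      [-360, 430],
      [60, 535],
      [480, 600]
    ],
    "landmarks": [
      [0, 0],
      [400, 300],
      [480, 600],
      [40, 1320],
      [-400, 740],
      [-360, 430]
    ],
    "subregions": {}
  },
  "posterior": {
    "outline": [
      [0, 0],
      [231, 94.5],
      [420, 315],
      [504, 798],
      [451.5, 997.5],
      [273, 1260],
      [42, 1386],
      [-178.5, 1323],
      [-346.5, 1092],
      [-420, 777],
      [-378, 588],
      [-199.5, 147]
    ],
    "la": [
      [0, 0],
      [231, 94.5],
      [420, 315],
      [504, 798],
      [63, 714],
      [-378, 588],
      [-199.5, 147]
    ],
    "ba": [
      [504, 798],
      [451.5, 997.5],
      [273, 1260],
      [42, 1386],
      [-178.5, 1323],
      [-346.5, 1092],
      [-420, 777],
      [-378, 588],
      [63, 714]
    ],
    "border": [
      [-378, 588],
      [63, 714],
      [504, 798]
    ],
    "landmarks": [
      [0, 0],
      [420, 315],
      [504, 798],
      [42, 1386],
      [-420, 777],
      [-378, 588]
    ],
    "subregions": {}
  }
}
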