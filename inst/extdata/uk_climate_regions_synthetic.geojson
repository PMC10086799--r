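{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "region": "East Anglia",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-0.5, 52.2],
            [1.8, 52.2],
            [1.8, 53.5],
            [-0.5, 53.5],
            [-0.5, 52.2]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "East & NE England",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-2.2, 53.5],
            [1.8, 53.5],
            [1.8, 55.5],
            [-2.2, 55.5],
            [-2.2, 53.5]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "NW England & N Wales",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-6.5, 53.5],
            [-2.2, 53.5],
            [-2.2, 55.5],
            [-6.5, 55.5],
            [-6.5, 53.5]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "SE & Central England",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-1.5, 49.8],
            [1.8, 49.8],
            [1.8, 52.2],
            [-1.5, 52.2],
            [-1.5, 49.8]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "Midlands",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-6.5, 52.2],
            [-0.5, 52.2],
            [-0.5, 53.5],
            [-6.5, 53.5],
            [-6.5, 52.2]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "S Wales & SW England",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-6.5, 49.8],
            [-1.5, 49.8],
            [-1.5, 52.2],
            [-6.5, 52.2],
            [-6.5, 49.8]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "East Scotland",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-4, 55.5],
            [1.8, 55.5],
            [1.8, 57],
            [-4, 57],
            [-4, 55.5]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "North Scotland",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-4, 57],
            [1.8, 57],
            [1.8, 58.8],
            [-4, 58.8],
            [-4, 57]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {
        "region": "West Scotland",
        "note": "synthetic simplified box geometry, not Met Office boundaries"
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [-6.5, 55.5],
            [-4, 55.5],
            [-4, 58.8],
            [-6.5, 58.8],
            [-6.5, 55.5]
          ]
        ]
      }
    }
  ]
}
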