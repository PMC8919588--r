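{
  "type": "FeatureCollection",
  "name": "Synthetic coarse land mask, Indian Ocean window (lon 20-130 E, lat 45 S - 35 N). Hand-simplified continental outlines for simulation and masking; NOT a cartographic product.",
  "features": [
    {"type": "Feature", "properties": {"name": "africa_east"}, "geometry": {"type": "Polygon", "coordinates": [[
      [20.0,-36.0],[27.0,-34.0],[32.0,-28.5],[35.5,-24.0],[36.3,-18.5],[40.5,-15.5],
      [40.7,-10.5],[39.2,-6.5],[41.5,-1.7],[46.0,4.5],[51.4,11.8],[43.4,11.5],
      [39.0,15.0],[37.0,18.0],[35.0,24.0],[32.3,29.5],[20.0,33.0],[20.0,-36.0]
    ]]}},
    {"type": "Feature", "properties": {"name": "arabia"}, "geometry": {"type": "Polygon", "coordinates": [[
      [43.3,12.5],[45.2,12.9],[52.2,15.6],[55.1,17.0],[57.8,18.9],[59.8,22.3],
      [58.0,23.7],[56.4,26.5],[51.5,28.0],[48.0,29.5],[44.0,31.0],[36.0,32.0],
      [34.9,29.4],[36.0,27.0],[39.0,20.0],[41.5,16.0],[43.3,12.5]
    ]]}},
    {"type": "Feature", "properties": {"name": "south_asia_mainland"}, "geometry": {"type": "Polygon", "coordinates": [[
      [48.0,30.0],[52.0,27.0],[56.5,27.0],[61.6,25.2],[66.5,24.8],[67.5,23.8],
      [70.0,22.8],[72.6,19.9],[73.5,15.5],[74.9,12.8],[76.5,9.5],[77.5,8.1],
      [80.3,13.4],[82.3,16.5],[86.0,19.8],[88.0,21.6],[91.8,22.3],[92.3,20.2],
      [94.2,16.0],[97.6,16.5],[98.2,13.0],[98.5,10.0],[99.2,9.0],[100.4,13.5],
      [102.5,12.0],[105.0,10.0],[106.8,10.5],[109.5,13.0],[108.0,21.0],[110.0,25.0],
      [105.0,30.0],[48.0,30.0]
    ]]}},
    {"type": "Feature", "properties": {"name": "sri_lanka"}, "geometry": {"type": "Polygon", "coordinates": [[
      [79.8,9.1],[81.9,8.6],[81.7,6.1],[80.2,5.9],[79.8,9.1]
    ]]}},
    {"type": "Feature", "properties": {"name": "madagascar"}, "geometry": {"type": "Polygon", "coordinates": [[
      [43.2,-16.1],[46.3,-13.8],[49.9,-12.9],[50.5,-15.7],[49.6,-19.0],[47.1,-24.9],
      [45.1,-25.6],[43.2,-22.3],[43.2,-16.1]
    ]]}},
    {"type": "Feature", "properties": {"name": "sumatra"}, "geometry": {"type": "Polygon", "coordinates": [[
      [95.2,5.6],[97.5,5.2],[100.6,2.1],[103.5,-0.8],[106.0,-3.0],[106.0,-6.0],
      [104.5,-5.6],[102.0,-4.0],[98.7,0.2],[95.9,2.9],[95.2,5.6]
    ]]}},
    {"type": "Feature", "properties": {"name": "java_lesser_sunda"}, "geometry": {"type": "Polygon", "coordinates": [[
      [105.1,-6.8],[110.0,-6.9],[114.4,-7.7],[116.5,-8.8],[119.0,-8.4],[123.0,-10.2],
      [125.0,-9.5],[124.5,-8.5],[120.0,-7.5],[114.0,-6.5],[108.0,-6.0],[105.1,-6.8]
    ]]}},
    {"type": "Feature", "properties": {"name": "borneo"}, "geometry": {"type": "Polygon", "coordinates": [[
      [109.0,1.8],[111.0,1.3],[113.0,3.3],[117.5,7.0],[119.2,5.3],[117.8,3.0],
      [116.3,-2.0],[114.0,-3.7],[110.2,-1.5],[109.0,1.8]
    ]]}},
    {"type": "Feature", "properties": {"name": "australia_west"}, "geometry": {"type": "Polygon", "coordinates": [[
      [113.2,-21.9],[113.8,-26.3],[115.0,-30.0],[115.1,-34.3],[118.0,-35.0],[124.0,-33.0],
      [129.0,-31.7],[130.0,-31.7],[130.0,-12.4],[126.5,-14.0],[123.5,-16.5],[120.9,-19.7],
      [116.7,-20.7],[113.2,-21.9]
    ]]}}
  ]
}
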