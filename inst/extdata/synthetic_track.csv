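id,timestamp,x,y
synthetic01,2020-05-01T00:00:00,584600,4510000
synthetic01,2020-05-01T00:15:00,584445.4,4510087.3
synthetic01,2020-05-01T00:30:00,584376.4,4509985.4
synthetic01,2020-05-01T00:45:00,584436.4,4509948.1
synthetic01,2020-05-01T01:00:00,584385.3,4509960
synthetic01,2020-05-01T01:15:00,584498.9,4509755.8
synthetic01,2020-05-01T01:30:00,584556.3,4509819.8
synthetic01,2020-05-01T01:45:00,584287.4,4509803.4
synthetic01,2020-05-01T02:00:00,584249.3,4509759.9
synthetic01,2020-05-01T02:15:00,584067.6,4509789.6
synthetic01,2020-05-01T02:30:00,584383.4,4509853
synthetic01,2020-05-01T02:45:00,584390.4,4509863.5
synthetic01,2020-05-01T03:00:00,584487,4509923.1
synthetic01,2020-05-01T03:15:00,584322.7,4510024.1
synthetic01,2020-05-01T03:30:00,584399.8,4509944
synthetic01,2020-05-01T03:45:00,584467.3,4509920.2
synthetic01,2020-05-01T04:00:00,584464.3,4509834.4
synthetic01,2020-05-01T04:15:00,584331.6,4509869
synthetic01,2020-05-01T04:30:00,584233.1,4509646.4
synthetic01,2020-05-01T04:45:00,584534.4,4509823.7
synthetic01,2020-05-01T05:00:00,584585.2,4509583.8
synthetic01,2020-05-01T05:15:00,584553.5,4509830.3
synthetic01,2020-05-01T05:30:00,584559.3,4510067.9
synthetic01,2020-05-01T05:45:00,584490.4,4510095.5
synthetic01,2020-05-01T06:00:00,584683.4,4510220.6
synthetic01,2020-05-01T06:15:00,584887.8,4510156.9
synthetic01,2020-05-01T06:30:00,584930.2,4510183.7
synthetic01,2020-05-01T06:45:00,585104.7,4510226
synthetic01,2020-05-01T07:00:00,585195.1,4510007.9
synthetic01,2020-05-01T07:15:00,585194.4,4510158.6
synthetic01,2020-05-01T07:30:00,585302.3,4510073.3
synthetic01,2020-05-01T07:45:00,585319.5,4510200.8
synthetic01,2020-05-01T08:00:00,585338,4510216.5
synthetic01,2020-05-01T08:15:00,585265.5,4510193.1
synthetic01,2020-05-01T08:30:00,585396.4,4510242.5
synthetic01,2020-05-01T08:45:00,585602.6,4510217.5
synthetic01,2020-05-01T09:00:00,585463.5,4510336.4
synthetic01,2020-05-01T09:15:00,585169.7,4510131.7
synthetic01,2020-05-01T09:30:00,585058.2,4510287
synthetic01,2020-05-01T09:45:00,585281.2,4510241.7
synthetic01,2020-05-01T10:00:00,585316.8,4510170.7
synthetic01,2020-05-01T10:15:00,585436.3,4509916.4
synthetic01,2020-05-01T10:30:00,585327.8,4509748.4
synthetic01,2020-05-01T10:45:00,585333.1,4509713.7
synthetic01,2020-05-01T11:00:00,585414.6,4509806.8
synthetic01,2020-05-01T11:15:00,585416.4,4510004.4
synthetic01,2020-05-01T11:30:00,585281.1,4510032.1
synthetic01,2020-05-01T11:45:00,585353,4510269.7
synthetic01,2020-05-01T12:00:00,585568,4510205.7
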