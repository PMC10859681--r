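group,feature,manual,semiauto,clahe
glcm,autocorrelation,0.677,0.761,0.961
glcm,contrast,0.183,0.502,0.998
glcm,correlation,0.678,0.781,0.982
glcm,cluster_prominence,0.674,0.797,0.855
glcm,cluster_shade,0.693,0.753,0.808
glcm,dissimilarity,0.592,0.892,0.988
glcm,energy,0.174,0.351,0.978
glcm,entropy,0.704,0.804,0.963
glcm,homogeneity,0.655,0.756,0.987
glcm,maximum_probability,0.622,0.822,0.989
glcm,sum_of_squares,0.204,0.604,0.927
glcm,sum_average,0.698,0.804,0.916
glcm,sum_variance,0.298,0.698,0.986
glcm,sum_entropy,0.662,0.762,0.887
glcm,difference_variance,0.672,0.772,0.998
glcm,difference_entropy,0.603,0.803,0.898
glcm,imc1,0.623,0.823,0.899
glcm,imc2,0.678,0.888,0.911
glcm,idn,0.734,0.834,0.998
glcm,idmn,0.878,0.978,0.979
first_order,mean,0.805,0.875,0.989
first_order,variance,0.842,0.842,0.999
first_order,skewness,0.806,0.806,0.994
first_order,kurtosis,0.846,0.846,0.971
first_order,energy,0.841,0.811,0.979
first_order,entropy,0.837,0.837,0.981
shape,area,0.886,0.807,0.987
shape,major_axis_length,0.868,0.868,0.908
shape,minor_axis_length,0.893,0.793,0.942
shape,eccentricity,0.244,0.649,0.834
shape,orientation,0.162,0.662,0.963
shape,convex_area,0.169,0.569,0.949
shape,equiv_diameter,0.104,0.678,0.999
shape,perimeter,0.666,0.766,0.959
shape,solidity,0.805,0.605,0.833
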