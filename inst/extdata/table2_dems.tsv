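mirna	log2fc_early	adj_p_early	log2fc_advanced	adj_p_advanced
miR-135b-5p	5.6076	3.68e-6	4.5955	3.79e-5
miR-1246	3.5486	4.66e-4	3.1755	9.40e-4
miR-320e	3.3997	1.23e-3	1.9946	4.15e-2
miR-20a-5p + miR-20b-5p	3.2894	2.73e-4	2.548	2.26e-3
miR-4286	2.9336	2.73e-4	3.139	3.79e-5
miR-146a-5p	2.5624	2.01e-3	2.0579	9.86e-3
miR-19a-3p	2.4022	4.91e-3	1.7884	3.42e-2
miR-106b-5p	2.3721	2.03e-3	2.133	4.45e-3
miR-106a-5p + miR-17-5p	1.9845	1.18e-2	1.9664	1.06e-2
miR-155-5p	1.6139	3.89e-2	1.5258	4.11e-2
miR-451a	-1.613	4.91e-3	-2.183	1.23e-4
let-7c-5p	-1.7823	3.41e-2	-1.8153	2.62e-2
miR-143-3p	-2.277	1.10e-2	-3.3435	1.27e-4
miR-376a-3p	-2.2942	2.47e-3	-2.851	1.23e-4
miR-125b-5p	-2.3358	4.91e-3	-2.6988	9.40e-4
miR-493-3p	-2.4092	1.18e-2	-1.8694	4.43e-2
miR-99a-5p	-2.493	5.15e-3	-2.9023	9.40e-4
miR-100-5p	-2.9476	2.47e-3	-2.1328	2.62e-2
miR-145-5p	-3.0946	2.01e-3	-4.2751	2.80e-5
miR-133a-3p	-3.4162	2.70e-5	-3.5457	1.04e-5
miR-127-3p	-3.6761	1.20e-3	-2.7343	9.59e-3
miR-429	3.4377	4.16e-4	NS	NS
miR-7-5p	3.2314	4.91e-3	NS	NS
miR-200a-3p	3.1361	1.53e-3	NS	NS
miR-200b-3p	2.8625	1.58e-3	NS	NS
miR-215-5p	2.7648	1.23e-2	NS	NS
miR-141-3p	2.7289	2.01e-3	NS	NS
miR-1915-3p	2.6009	4.58e-2	NS	NS
miR-148a-3p	2.5557	4.91e-3	NS	NS
miR-19b-3p	2.3694	1.70e-2	NS	NS
miR-4284	2.3229	1.26e-2	NS	NS
miR-4488	2.2396	3.81e-2	NS	NS
miR-192-5p	2.2229	5.71e-3	NS	NS
miR-93-5p	1.9035	5.71e-3	NS	NS
miR-331-3p	1.7912	1.19e-2	NS	NS
miR-574-5p	1.6117	4.81e-2	NS	NS
miR-181b-5p + miR-181d-5p	1.6065	3.66e-2	NS	NS
miR-218-5p	-1.6599	4.81e-2	NS	NS
miR-1260a	-1.6987	4.81e-2	NS	NS
miR-299-5p	-1.7928	4.81e-2	NS	NS
miR-132-3p	-2.4327	1.58e-3	NS	NS
miR-539-5p	-2.5299	1.23e-2	NS	NS
miR-551b-3p	-2.6493	5.88e-3	NS	NS
miR-122-5p	NS	NS	4.3823	9.47e-3
miR-424-5p	NS	NS	2.6376	7.13e-3
miR-196a-5p	NS	NS	2.1378	3.92e-2
miR-503-5p	NS	NS	1.8254	9.35e-3
miR-190a-5p	NS	NS	1.7435	2.62e-2
miR-494-3p	NS	NS	1.7188	3.42e-2
miR-450a-5p	NS	NS	1.5561	1.20e-2
miR-199a-5p	NS	NS	-1.2596	4.47e-2
miR-126-3p	NS	NS	-1.3007	3.42e-2
miR-150-5p	NS	NS	-1.3628	3.85e-2
miR-23b-3p	NS	NS	-1.49	2.62e-2
miR-29c-3p	NS	NS	-1.5053	4.05e-2
miR-365a-3p + miR-365b-3p	NS	NS	-1.5083	4.15e-2
miR-199b-5p	NS	NS	-1.7306	3.74e-2
miR-337-5p	NS	NS	-1.8124	4.06e-2
miR-495-3p	NS	NS	-1.8206	2.38e-2
miR-342-3p	NS	NS	-1.9453	3.35e-3
miR-125a-5p	NS	NS	-1.9477	2.84e-2
miR-30d-5p	NS	NS	-2.0007	9.35e-3
miR-99b-5p	NS	NS	-2.0074	5.41e-3
miR-497-5p	NS	NS	-2.0825	4.08e-3
miR-194-5p	NS	NS	-2.2212	4.43e-2
miR-195-5p	NS	NS	-2.2899	2.06e-2
miR-10b-5p	NS	NS	-2.519	1.69e-3
miR-574-3p	NS	NS	-3.6247	1.23e-4
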