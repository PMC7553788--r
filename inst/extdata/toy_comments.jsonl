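{"id":"c1","timestamp":"2020-03-01","source":"reddit_comment","title":"","body":"ok thanks","score":1,"comment_count":0,"author_id":"u5"}
{"id":"c2","timestamp":"2020-03-01","source":"reddit_comment","title":"","body":"ok thanks!","score":2,"comment_count":0,"author_id":"u6"}
{"id":"c3","timestamp":"2020-03-02","source":"reddit_comment","title":"","body":"Please wear a mask.","score":1,"comment_count":0,"author_id":"u7"}
{"id":"c4","timestamp":"2020-03-02","source":"reddit_comment","title":"","body":"Please wear a mask.","score":1,"comment_count":0,"author_id":"u7"}
{"id":"c5","timestamp":"2020-03-03","source":"reddit_comment","title":"","body":"Please wear a mask.","score":1,"comment_count":0,"author_id":"u7"}
{"id":"c6","timestamp":"2020-03-04","source":"reddit_comment","title":"","body":"Please wear a mask.","score":1,"comment_count":0,"author_id":"u7"}
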